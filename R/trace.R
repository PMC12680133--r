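# Vectorial ray tracing of the folded dOPM collection path.
#
# Every ray carries a unit wavevector k and a transverse complex electric
# field 3-vector. Optical elements act as per-ray 3x3 operators:
# objectives rotate the field in the meridional plane (the plane containing
# the ray and the lens axis), the PBS and quarter-wave plate act on lab
# transverse coordinates, and the tilted mirror applies complex s/p
# reflection coefficients in the per-ray plane of incidence together with a
# Householder reflection of the wavevector. Composing the chain per ray
# gives a single operator A; summing output energies incoherently over a
# dipole ensemble reduces to tr(A^H A M) with M the (weighted) dipole
# second-moment matrix, which makes the full 15,000-ray x 7,500-dipole
# simulation a vectorized O(n_rays) computation.

# ---- small vectorized linear-algebra helpers (n x 3 / n x 3 x 3) ----

vnorm <- function(v) sqrt(rowSums(Re(v * Conj(v))))

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# C = B %*% A per ray, arrays n x 3 x 3
ray_matmul <- function(B, A) {
  n <- dim(A)[1]
  C <- array(0i, dim = c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + B[, i, k] * A[, k, j]
    C[, i, j] <- acc
  }
  C
}

# outer products u v^T per ray -> n x 3 x 3
ray_outer <- function(u, v) {
  n <- nrow(u)
  A <- array(0i, dim = c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) A[, i, j] <- u[, i] * v[, j]
  A
}

# per-ray scalar * operator
ray_scale <- function(s, A) {
  for (i in 1:3) for (j in 1:3) A[, i, j] <- s * A[, i, j]
  A
}

ray_identity <- function(n) {
  A <- array(0i, dim = c(n, 3, 3))
  for (i in 1:3) A[, i, i] <- 1 + 0i
  A
}

# constant 3x3 matrix applied to all rays
ray_const <- function(n, m) {
  A <- array(0i, dim = c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) A[, i, j] <- m[i, j]
  A
}

#' Meridional rotation operators for a high-NA lens
#'
#' An ideal aplanatic lens rotates each ray's electric field in its
#' meridional plane (the plane containing the ray and the lens axis),
#' leaving the azimuthal (s) component unchanged: collimation rotates the
#' wavevector onto the lens axis, focusing is the inverse. This returns the
#' per-ray 3x3 rotation (Rodrigues form about the axis `k x axis`).
#'
#' @param k `n x 3` matrix of unit ray directions.
#' @param axis Length-3 unit lens axis (the direction of collimated
#'   propagation; use `c(0, 0, -1)` for a beam travelling backwards).
#' @param collimate If `TRUE`, returns the rotation mapping each `k` onto
#'   `axis`; if `FALSE` its inverse (focusing).
#' @return `n x 3 x 3` array of rotation operators.
#' @export
meridional_rotation <- function(k, axis = c(0, 0, 1), collimate = TRUE) {
  stopifnot(is.matrix(k), ncol(k) == 3, length(axis) == 3)
  axis <- axis / sqrt(sum(axis^2))
  n <- nrow(k)
  axm <- matrix(axis, n, 3, byrow = TRUE)
  a <- vcross(k, axm)          # rotation axis (unnormalized), |a| = sin
  sinA <- vnorm(a)
  cosA <- as.numeric(k %*% axis)
  ok <- sinA > 1e-12
  ahat <- a
  ahat[ok, ] <- a[ok, ] / sinA[ok]
  ahat[!ok, ] <- 0
  # Rodrigues: R = cos I + sin [a]_x + (1 - cos) a a^T
  R <- array(0i, dim = c(n, 3, 3))
  for (i in 1:3) R[, i, i] <- cosA
  R[, 1, 2] <- R[, 1, 2] - sinA * ahat[, 3]
  R[, 1, 3] <- R[, 1, 3] + sinA * ahat[, 2]
  R[, 2, 1] <- R[, 2, 1] + sinA * ahat[, 3]
  R[, 2, 3] <- R[, 2, 3] - sinA * ahat[, 1]
  R[, 3, 1] <- R[, 3, 1] - sinA * ahat[, 2]
  R[, 3, 2] <- R[, 3, 2] + sinA * ahat[, 1]
  for (i in 1:3) for (j in 1:3)
    R[, i, j] <- R[, i, j] + (1 - cosA) * ahat[, i] * ahat[, j]
  # degenerate rays parallel to the axis: identity (or -flip if antiparallel)
  deg <- !ok
  if (any(deg)) {
    anti <- deg & (cosA < 0)
    for (i in 1:3) for (j in 1:3) R[deg, i, j] <- 0
    for (i in 1:3) R[deg, i, i] <- 1
    # antiparallel degenerate rays: rotate by pi about x
    if (any(anti)) { R[anti, 2, 2] <- -1; R[anti, 3, 3] <- -1 }
  }
  if (!collimate) R <- aperm(R, c(1, 3, 2))  # inverse = transpose
  R
}

#' Jones operator of a waveplate in lab coordinates
#'
#' Waveplate acting on the transverse (x, y) field components of a
#' collimated beam along z, with given retardance and fast-axis angle.
#' Returned as a 3x3 matrix that leaves the z component unchanged.
#'
#' @param retardance_deg Retardance in degrees (90 for a quarter-wave
#'   plate, 180 for a half-wave plate).
#' @param fast_axis_deg Fast-axis angle from x, degrees.
#' @return A complex 3x3 matrix.
#' @export
jones_waveplate <- function(retardance_deg = 90, fast_axis_deg = 45) {
  phi <- retardance_deg * pi / 180
  a <- fast_axis_deg * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  J <- Rm %*% diag(c(1 + 0i, exp(1i * phi))) %*% t(Rm)
  out <- diag(3) + 0i
  out[1:2, 1:2] <- J
  out
}

#' Jones operator of an ideal linear polarizer / PBS port
#'
#' Projector onto a transmission axis in the transverse plane, as a 3x3
#' matrix (the z component is discarded).
#'
#' @param axis Length-3 transmission axis (z component must be zero).
#' @return A complex 3x3 projector.
#' @export
jones_polarizer <- function(axis = c(1, 0, 0)) {
  stopifnot(length(axis) == 3, axis[3] == 0)
  axis <- axis / sqrt(sum(axis^2))
  outer(axis, axis) + 0i
}

#' Coated tilted-mirror element
#'
#' Reflect rays off a flat mirror with unit normal `normal` and coating
#' `stack`: the wavevector transforms by the Householder reflection
#' `k - 2 (k . n) n`, and the field picks up the complex s/p reflection
#' coefficients of the coating in the per-ray plane of incidence
#' (s perpendicular to it, p within it).
#'
#' @param k `n x 3` matrix of unit incident ray directions.
#' @param normal Length-3 unit mirror normal.
#' @param stack A [coating_stack()].
#' @param wavelength_nm Vacuum wavelength, nm.
#' @return List with `op` (`n x 3 x 3` field operators) and `k_out`
#'   (`n x 3` reflected unit directions).
#' @export
mirror_element <- function(k, normal, stack = coating_presets("perfect"),
                           wavelength_nm = 520) {
  stopifnot(is.matrix(k), ncol(k) == 3, length(normal) == 3)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-9)
    stop("`normal` must be a unit vector")
  n <- nrow(k)
  nm <- matrix(normal, n, 3, byrow = TRUE)
  kn <- as.numeric(k %*% normal)
  k_out <- k - 2 * kn * nm
  inc_deg <- acos(pmin(1, abs(kn))) * 180 / pi
  inc_deg <- pmin(inc_deg, 90 - 1e-9)
  r_s <- coating_reflectivity(stack, inc_deg, wavelength_nm, "s")
  r_p <- coating_reflectivity(stack, inc_deg, wavelength_nm, "p")

  s <- vcross(k, nm)
  slen <- vnorm(s)
  deg <- slen < 1e-12
  s[!deg, ] <- s[!deg, ] / slen[!deg]
  if (any(deg)) {
    # normal incidence: any axis perpendicular to the normal will do
    alt <- vcross(nm[deg, , drop = FALSE],
                  matrix(c(0, 1, 0), sum(deg), 3, byrow = TRUE))
    bad <- vnorm(alt) < 1e-9
    if (any(bad))
      alt[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    s[deg, ] <- alt / vnorm(alt)
  }
  p_in <- vcross(s, k)        # p basis before reflection
  p_out <- -vcross(s, k_out)  # p basis after reflection (sign convention
                              # matches r_p = r_s at normal incidence)
  op <- ray_outer(s, s)
  op <- ray_scale(r_s, op)
  opp <- ray_scale(r_p, ray_outer(p_out, p_in))
  op <- op + opp
  list(op = op, k_out = k_out)
}

# ---- ray fans and dipole ensembles ----

#' Hemispherical ray fan overfilling the primary pupil
#'
#' Deterministic Fibonacci fan of ray directions over the full upper
#' hemisphere (2 pi steradians), overfilling the primary collection cone;
#' each ray is tagged as inside or outside that cone. Each ray represents
#' an equal element of solid angle.
#'
#' @param geometry A [system_geometry()].
#' @param n Number of rays (default 15,000).
#' @return List with `k` (`n x 3` unit directions) and `inside_o1`
#'   (logical).
#' @export
build_ray_fan <- function(geometry, n = 15000) {
  stopifnot(inherits(geometry, "system_geometry"))
  k <- fibonacci_directions(n, 90)
  a1 <- half_angle(geometry$primary$na, geometry$primary$immersion_index)
  list(k = k, inside_o1 = k[, 3] >= cospi(a1 / 180))
}

#' Dipole-emitter ensemble
#'
#' Deterministic ensemble of electric-dipole emitters with orientations
#' filling a hemisphere on a Fibonacci lattice. In the `"tumbling"` regime
#' (emission fully depolarized by rotational diffusion) all dipoles carry
#' equal weight; in the `"static"` regime the weights follow photoselection
#' by linearly polarized excitation, `w = |d . e_exc|^2`.
#'
#' @param n Number of dipoles (default 7,500).
#' @param regime `"tumbling"` or `"static"`.
#' @param excitation Length-3 excitation polarization direction (static
#'   regime); the default `x` is the in-sheet lab axis, which coincides
#'   with the PBS transmission axis.
#' @return List with `d` (`n x 3` unit orientations), `weights`, `regime`.
#' @export
dipole_ensemble <- function(n = 7500, regime = c("tumbling", "static"),
                            excitation = c(1, 0, 0)) {
  regime <- match.arg(regime)
  d <- fibonacci_directions(n, 90)
  if (regime == "tumbling") {
    w <- rep(1, n)
  } else {
    if (sqrt(sum(excitation^2)) < 1e-12)
      stop("zero-norm excitation vector in static regime")
    e <- excitation / sqrt(sum(excitation^2))
    w <- as.numeric(d %*% e)^2
  }
  list(d = d, weights = w, regime = regime)
}

#' Far-field dipole radiation polarization
#'
#' Transverse projection of the dipole moment onto the plane perpendicular
#' to the emission direction: `E` is proportional to `k x (d x k)`, i.e.
#' `d - (k . d) k`, with magnitude proportional to the sine of the angle
#' between dipole and ray.
#'
#' @param d_hat Length-3 (or `n x 3`) unit dipole orientation.
#' @param k_hat Length-3 (or `n x 3`) unit emission direction.
#' @return Field vector(s), same shape as the broadcast inputs.
#' @export
dipole_farfield <- function(d_hat, k_hat) {
  d <- if (is.matrix(d_hat)) d_hat else matrix(d_hat, 1)
  k <- if (is.matrix(k_hat)) k_hat else matrix(k_hat, 1)
  n <- max(nrow(d), nrow(k))
  if (nrow(d) == 1L) d <- d[rep(1L, n), , drop = FALSE]
  if (nrow(k) == 1L) k <- k[rep(1L, n), , drop = FALSE]
  kd <- rowSums(k * d)
  E <- d - kd * k
  if (!is.matrix(d_hat) && !is.matrix(k_hat)) drop(E) else E
}

# weighted dipole second-moment matrix M = sum_i w_i d_i d_i^T
dipole_second_moment <- function(ensemble) {
  d <- ensemble$d
  crossprod(d * sqrt(ensemble$weights))
}

# ---- the composed collection chain ----

#' Per-ray composed operator of the dOPM collection path
#'
#' Compose, for every ray of a hemispherical fan, the 3x3 operator of the
#' full collection chain: primary objective (meridional collimation), PBS
#' transmission port, quarter-wave plate, secondary objective (focusing
#' into remote space), coated tilted mirror (normal at half the OPM angle),
#' tertiary objective (re-collimation of the reflected, backwards
#' travelling beam), second quarter-wave plate pass and PBS reflection
#' port. Rays blocked by any pupil carry a zero operator.
#'
#' Tube and relay lenses are polarization-neutral and omitted. Ray energies
#' are carried in solid-angle measure, so ideal lenses conserve energy per
#' ray and no apodization factor enters the energy bookkeeping.
#'
#' @param geometry A [system_geometry()].
#' @param mirror A [coating_stack()] for the fold mirror.
#' @param wavelength_nm Vacuum wavelength, nm (default 520, mid-band of
#'   green fluorescent-protein emission).
#' @param n_rays Number of rays in the hemispherical fan.
#' @param pbs,qwp Set `FALSE` to remove the PBS ports and/or the
#'   quarter-wave plate (used for energy-conservation checks).
#' @return List of class `dopm_chain` with `k` (input directions), `k_out`
#'   (directions after the mirror), `A` (per-ray composed operators,
#'   `n x 3 x 3`), `inside_o1`, `passes` (logical, survived all pupils),
#'   and the geometry.
#' @export
precompute_chain <- function(geometry, mirror = coating_presets("perfect"),
                             wavelength_nm = 520, n_rays = 15000,
                             pbs = TRUE, qwp = TRUE) {
  stopifnot(inherits(geometry, "system_geometry"),
            inherits(mirror, "coating_stack"))
  fan <- build_ray_fan(geometry, n_rays)
  k <- fan$k
  n <- nrow(k)
  a3 <- half_angle(geometry$secondary_tertiary$na,
                   geometry$secondary_tertiary$immersion_index)
  ca3 <- cospi(a3 / 180)
  theta <- geometry$opm_angle_deg
  normal <- c(sinpi(theta / 360), 0, cospi(theta / 360))

  # start from the transverse projector T_k = I - k k^T so that applying
  # the chain to a raw dipole moment directly yields the collected field
  A <- ray_identity(n) - ray_outer(k, k)

  # primary objective: meridional collimation onto +z
  A <- ray_matmul(meridional_rotation(k, c(0, 0, 1), collimate = TRUE), A)
  if (pbs) A <- ray_matmul(ray_const(n, jones_polarizer(c(1, 0, 0))), A)
  if (qwp) A <- ray_matmul(ray_const(n, jones_waveplate(90, 45)), A)

  # secondary objective: focus into remote space (rays outside its cone
  # are clipped); under remote refocusing each ray regains its direction
  in_o2 <- k[, 3] >= ca3
  A <- ray_matmul(meridional_rotation(k, c(0, 0, 1), collimate = FALSE), A)

  mir <- mirror_element(k, normal, mirror, wavelength_nm)
  A <- ray_matmul(mir$op, A)
  k_out <- mir$k_out

  # tertiary pass through the same objective: the reflected beam travels
  # backwards; accept rays within the cone about -z and re-collimate
  in_o3 <- -k_out[, 3] >= ca3
  A <- ray_matmul(meridional_rotation(k_out, c(0, 0, -1), collimate = TRUE), A)
  if (qwp) A <- ray_matmul(ray_const(n, jones_waveplate(90, 45)), A)
  if (pbs) A <- ray_matmul(ray_const(n, jones_polarizer(c(0, 1, 0))), A)

  passes <- fan$inside_o1 & in_o2 & in_o3
  if (any(!passes)) for (i in 1:3) for (j in 1:3) A[!passes, i, j] <- 0

  structure(
    list(k = k, k_out = k_out, A = A, inside_o1 = fan$inside_o1,
         passes = passes, geometry = geometry, mirror = mirror,
         wavelength_nm = wavelength_nm, pbs = pbs, qwp = qwp),
    class = "dopm_chain")
}

# per-ray output energy and per-ray collected (input) energy for a dipole
# second-moment matrix M
chain_energies <- function(chain, M) {
  A <- chain$A
  k <- chain$k
  n <- nrow(k)
  # G = A^H A (per ray), energy_out = tr(G M)
  e_out <- numeric(n)
  for (i in 1:3) for (j in 1:3) {
    g <- 0
    for (l in 1:3) g <- g + Conj(A[, l, i]) * A[, l, j]
    e_out <- e_out + Re(g * M[j, i])
  }
  # input transverse energy per ray: tr(T_k M T_k) = tr(M) - k^T M k
  kMk <- numeric(n)
  for (i in 1:3) for (j in 1:3) kMk <- kMk + k[, i] * M[i, j] * k[, j]
  e_in <- sum(diag(M)) - kMk
  list(out = pmax(0, e_out), collected = pmax(0, e_in))
}

#' Ensemble collection efficiency from the vectorial trace
#'
#' Weighted incoherent sum, over a dipole ensemble and a hemispherical ray
#' fan, of the energy reaching the tertiary pupil after the full folded
#' collection chain, divided by the energy collected by the primary
#' objective. Optionally scaled by the measured optics transmission
#' `t_optics = T_o23^2 * T_pbs` (see [transmission_budget()]).
#'
#' For an ideal system at a 0 degree OPM angle this yields 50 percent for
#' rapidly tumbling fluorophores (a per-ray algebraic identity of the
#' PBS/QWP double pass) and about 71 percent for static photoselected
#' fluorophores with the 1.2 NA water-immersion primary; the paraxial
#' static limit is 75 percent ([pbs_lowna_transmission()]).
#'
#' @inheritParams precompute_chain
#' @param regime `"tumbling"` or `"static"` (photoselected) dipole
#'   ensemble.
#' @param include_t_optics If `TRUE`, scale by the measured transmissions.
#' @param n_dipoles Number of dipole orientations (default 7,500).
#' @param excitation Excitation polarization for the static regime.
#' @param chain Optionally a precomputed [precompute_chain()] result to
#'   reuse.
#' @return Object of class `efficiency_report`: list with
#'   `fraction_vs_o1`, `regime`, `includes_t_optics`, `opm_angle_deg`,
#'   `coating`, `n_rays`, `n_dipoles`.
#' @examples
#' geom0 <- dopm_geometry(0)
#' ensemble_efficiency(geom0, "tumbling", n_rays = 2000,
#'                     n_dipoles = 500)$fraction_vs_o1 # 0.5
#' @export
ensemble_efficiency <- function(geometry, regime = c("tumbling", "static"),
                                mirror = coating_presets("perfect"),
                                include_t_optics = FALSE,
                                wavelength_nm = 520,
                                n_rays = 15000, n_dipoles = 7500,
                                excitation = c(1, 0, 0),
                                pbs = TRUE, qwp = TRUE, chain = NULL) {
  regime <- match.arg(regime)
  if (n_dipoles < 1) stop("empty dipole ensemble")
  if (is.null(chain))
    chain <- precompute_chain(geometry, mirror, wavelength_nm, n_rays,
                              pbs = pbs, qwp = qwp)
  ens <- dipole_ensemble(n_dipoles, regime, excitation)
  M <- dipole_second_moment(ens)
  en <- chain_energies(chain, M)
  num <- sum(en$out)
  den <- sum(en$collected[chain$inside_o1])
  frac <- num / den
  if (include_t_optics)
    frac <- frac * transmission_budget(chain$geometry, regime)$t_optics
  structure(
    list(fraction_vs_o1 = frac, regime = regime,
         includes_t_optics = include_t_optics,
         opm_angle_deg = chain$geometry$opm_angle_deg,
         coating = chain$mirror$name,
         n_rays = nrow(chain$k), n_dipoles = n_dipoles),
    class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(
    "<efficiency_report> %.4f vs primary (%s, %s mirror, OPM %g deg%s)\n",
    x$fraction_vs_o1, x$regime, x$coating, x$opm_angle_deg,
    if (x$includes_t_optics) ", incl. T_optics" else ""))
  invisible(x)
}

#' Simulated intensity map in the tertiary pupil
#'
#' Bin the per-ray output energies of the collection chain over normalized
#' tertiary-pupil coordinates (the transverse components of the reflected
#' ray direction divided by the tertiary NA). The integral of the map
#' equals the collection efficiency times the energy collected by the
#' primary objective.
#'
#' @inheritParams ensemble_efficiency
#' @param n_bins Number of bins per pupil axis (`>= 8`).
#' @return Object of class `pupil_field`: list with `intensity`
#'   (`n_bins x n_bins`), bin `breaks`, `total_energy`, `o1_energy` and
#'   the efficiency implied by their ratio.
#' @export
pupil_map <- function(geometry, regime = c("tumbling", "static"),
                      mirror = coating_presets("perfect"),
                      wavelength_nm = 520, n_rays = 15000, n_dipoles = 7500,
                      excitation = c(1, 0, 0), n_bins = 64, chain = NULL) {
  regime <- match.arg(regime)
  if (n_bins < 8) stop("`n_bins` must be at least 8")
  if (is.null(chain))
    chain <- precompute_chain(geometry, mirror, wavelength_nm, n_rays)
  ens <- dipole_ensemble(n_dipoles, regime, excitation)
  M <- dipole_second_moment(ens)
  en <- chain_energies(chain, M)
  na3 <- chain$geometry$secondary_tertiary$na /
    chain$geometry$secondary_tertiary$immersion_index
  u <- chain$k_out[, 1] / na3
  v <- chain$k_out[, 2] / na3
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  keep <- chain$passes & u >= -1 & u <= 1 & v >= -1 & v <= 1
  iu <- pmin(n_bins, pmax(1L, findInterval(u[keep], breaks,
                                           rightmost.closed = TRUE)))
  iv <- pmin(n_bins, pmax(1L, findInterval(v[keep], breaks,
                                           rightmost.closed = TRUE)))
  img <- matrix(0, n_bins, n_bins)
  e <- en$out[keep]
  for (idx in seq_along(e))
    img[iu[idx], iv[idx]] <- img[iu[idx], iv[idx]] + e[idx]
  total <- sum(en$out)
  o1 <- sum(en$collected[chain$inside_o1])
  structure(
    list(intensity = img, breaks = breaks, total_energy = total,
         o1_energy = o1, efficiency = total / o1),
    class = "pupil_field")
}
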