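#' Collection-cone half angle
#'
#' Half angle of the collection cone of an objective, `asin(na / n)`, in the
#' medium of refractive index `n`.
#'
#' @param na Numerical aperture.
#' @param n Refractive index of the medium (defaults to 1).
#' @return Half angle in degrees.
#' @examples
#' half_angle(1.2, 1.333) # ~64.2 deg for the water-immersion primary
#' half_angle(0.95)       # ~71.8 deg for the air remote objective
#' @export
half_angle <- function(na, n = 1.0) {
  stopifnot(is.numeric(na), is.numeric(n))
  if (any(na <= 0)) stop("`na` must be positive")
  if (any(na > n)) stop("`na` cannot exceed the medium index `n`")
  asin(na / n) * 180 / pi
}

#' Solid angle of a circular cone
#'
#' Solid angle subtended by a right circular cone of given half angle:
#' `2 * pi * (1 - cos(alpha))` steradians. A hemisphere (90 degrees) gives
#' exactly `2 * pi`.
#'
#' @param half_angle_deg Cone half angle in degrees, in `[0, 90]`.
#' @return Solid angle in steradians.
#' @export
cone_solid_angle <- function(half_angle_deg) {
  stopifnot(is.numeric(half_angle_deg))
  if (any(half_angle_deg < 0 | half_angle_deg > 90))
    stop("`half_angle_deg` must lie in [0, 90]")
  2 * pi * (1 - cospi(half_angle_deg / 180))
}

#' Minimum usable OPM angle
#'
#' The light sheet must be steered within the aperture of the primary
#' objective, so the minimum angle between sheet and coverslip is the
#' complement of the primary collection-cone half angle:
#' `90 - asin(na / n)` degrees. For the 1.2 NA water-immersion primary this
#' is 25.8 degrees (26 degrees to printed precision), with no aperture left
#' over for forming a thin sheet at that limit.
#'
#' @param primary An [objective_spec()].
#' @return Minimum OPM angle in degrees.
#' @export
min_opm_angle <- function(primary) {
  stopifnot(inherits(primary, "objective_spec"))
  90 - half_angle(primary$na, primary$immersion_index)
}

#' Fold-mirror normal tilt
#'
#' The tilted prism mirror folds the remote arm so that the tertiary view
#' axis makes the OPM angle with the secondary axis; a reflection doubles
#' the tilt, so the mirror normal sits at half the OPM angle
#' (17.5 degrees for a 35 degree OPM angle, 22.5 for 45).
#'
#' @param opm_angle_deg OPM angle in degrees.
#' @return Mirror-normal tilt from the secondary/tertiary optical axis,
#'   degrees.
#' @export
mirror_normal_tilt <- function(opm_angle_deg) {
  stopifnot(is.numeric(opm_angle_deg))
  if (any(opm_angle_deg < 0 | opm_angle_deg >= 90))
    stop("`opm_angle_deg` must lie in [0, 90)")
  opm_angle_deg / 2
}

#' Angular separation between the two views
#'
#' The two dOPM views tilt symmetrically about the primary axis, so their
#' light-sheet planes (and detection axes) are separated by twice the OPM
#' angle; at 45 degrees the two sheets are orthogonal.
#'
#' @param opm_angle_deg OPM angle in degrees.
#' @return View separation in degrees.
#' @export
view_separation <- function(opm_angle_deg) {
  stopifnot(is.numeric(opm_angle_deg))
  if (any(opm_angle_deg < 0 | opm_angle_deg >= 90))
    stop("`opm_angle_deg` must lie in [0, 90)")
  2 * opm_angle_deg
}

#' Remote-refocusing magnification
#'
#' Aberration-free remote refocusing requires the magnification from sample
#' space to remote space to equal the ratio of refractive indices
#' (`n_sample / n_remote`), so that ray angles are preserved between the two
#' spaces. For water to air this is 1.333.
#'
#' @param n_sample Refractive index of the sample-space immersion medium.
#' @param n_remote Refractive index of the remote-space medium.
#' @return The required magnification (dimensionless).
#' @export
remote_magnification <- function(n_sample, n_remote = 1.0) {
  stopifnot(is.numeric(n_sample), is.numeric(n_remote))
  if (any(n_sample <= 0) || any(n_remote <= 0))
    stop("refractive indices must be positive")
  n_sample / n_remote
}

# Internal: cone half angles (deg) of the three collection cones in the
# shared angular space. Under the remote-refocusing condition ray angles are
# preserved between sample and remote space, so the primary cone can be
# compared directly with the secondary cone (coaxial) and the tertiary cone
# (axis tilted by the OPM angle).
cone_half_angles <- function(geometry) {
  list(
    primary  = half_angle(geometry$primary$na,
                          geometry$primary$immersion_index),
    remote   = half_angle(geometry$secondary_tertiary$na,
                          geometry$secondary_tertiary$immersion_index))
}

#' Effective numerical apertures of the dual-view aperture
#'
#' The collection aperture of one dOPM view is the intersection of the
#' primary collection cone with the (coaxial) secondary cone and the
#' tertiary cone whose axis is tilted by the OPM angle. Because the two
#' half-extents of this intersection differ, the effective NA is
#' anisotropic:
#' * the latitudinal NA measures the intersection half-extent perpendicular
#'   to the tilt plane;
#' * the longitudinal NA measures half the angular range of the in-plane
#'   intersection (about the tertiary axis), i.e. the angular intervals
#'   `[-a1, a1]` and `[theta - a3, theta + a3]` intersected, where `a1`,
#'   `a3` are the primary and tertiary half angles and `theta` the OPM
#'   angle.
#'
#' Both are reported as `n_sample * sin(half-extent)`. For the 1.2 NA water
#' primary and 0.95 air tertiary at a 35 degree OPM angle this gives
#' (1.2, 1.03).
#'
#' @param geometry A [system_geometry()].
#' @return Named list with `latitudinal_na` and `longitudinal_na`. If the
#'   cones do not intersect, both are zero and a warning is raised (so
#'   angle sweeps remain plottable).
#' @export
effective_nas <- function(geometry) {
  stopifnot(inherits(geometry, "system_geometry"))
  ang <- cone_half_angles(geometry)
  a1 <- ang$primary
  a3 <- ang$remote
  theta <- geometry$opm_angle_deg
  n1 <- geometry$primary$immersion_index

  # in-plane interval intersection about the tertiary axis
  lo <- max(-a1, theta - a3)
  hi <- min(a1, theta + a3)
  if (hi <= lo) {
    warning("collection cones do not intersect at OPM angle ",
            theta, " deg; effective NAs are zero", call. = FALSE)
    return(list(latitudinal_na = 0, longitudinal_na = 0))
  }
  long_half <- (hi - lo) / 2
  longitudinal_na <- n1 * sinpi(long_half / 180)

  # Perpendicular to the tilt plane: a direction with in-plane angle mu and
  # out-of-plane angle beta, d = (cos(b) sin(mu), sin(b), cos(b) cos(mu)),
  # lies in the primary cone iff cos(b) cos(mu) >= cos(a1) and in the
  # tertiary cone iff cos(b) cos(mu - theta) >= cos(a3). The latitudinal
  # half-extent is the maximum beta over the in-plane intersection.
  ca1 <- cospi(a1 / 180)
  ca3 <- cospi(a3 / 180)
  mu <- seq(lo, hi, length.out = 2001) * pi / 180
  b1 <- acos(pmin(1, ca1 / pmax(cos(mu), ca1)))
  b3 <- acos(pmin(1, ca3 / pmax(cos(mu - theta * pi / 180), ca3)))
  lat_half <- max(pmin(b1, b3)) * 180 / pi
  latitudinal_na <- n1 * sinpi(lat_half / 180)

  list(latitudinal_na = latitudinal_na, longitudinal_na = longitudinal_na)
}

#' Quasi-uniform directions on a spherical cap (Fibonacci lattice)
#'
#' Deterministic quasi-uniform sample of `n` unit vectors within the
#' spherical cap of given half angle about `+z`, constructed with the
#' golden-angle (Fibonacci) spiral: points are equally spaced in `cos(theta)`
#' over the cap and successive azimuths advance by the golden angle.
#'
#' @param n Number of directions (`>= 1`).
#' @param cap_half_angle_deg Cap half angle in degrees, in `(0, 180]`;
#'   180 covers the full sphere, 90 the upper hemisphere.
#' @return An `n x 3` matrix of unit row vectors.
#' @export
fibonacci_directions <- function(n, cap_half_angle_deg = 90) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 1) stop("`n` must be at least 1")
  if (cap_half_angle_deg <= 0 || cap_half_angle_deg > 180)
    stop("`cap_half_angle_deg` must lie in (0, 180]")
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  z <- 1 - (i / n) * (1 - cospi(cap_half_angle_deg / 180))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solid angle of the dual-view collection aperture
#'
#' Numerically computes the solid angle of the intersection of the three
#' collection cones (primary, coaxial secondary, tilted tertiary) on the
#' unit sphere, by quasi-uniform Fibonacci sampling of the primary cone cap
#' and counting directions that also fall inside the secondary and tertiary
#' cones.
#'
#' @param geometry A [system_geometry()].
#' @param n_points Number of lattice points over the primary cap
#'   (default `1e6`; values below `1e4` are refused because the quadrature
#'   error then exceeds the documented 1 percent accuracy floor).
#' @return An object of class `aperture_report`: list with `omega_opm` and
#'   `omega_o1` (steradians), `latitudinal_na`, `longitudinal_na`, and
#'   `view_separation_deg`.
#' @examples
#' rep35 <- intersection_solid_angle(dopm_geometry(35), n_points = 1e5)
#' rep35$omega_opm / rep35$omega_o1
#' @export
intersection_solid_angle <- function(geometry, n_points = 1e6) {
  stopifnot(inherits(geometry, "system_geometry"))
  if (n_points < 1e4)
    stop("`n_points` below the documented accuracy floor of 1e4")
  ang <- cone_half_angles(geometry)
  a1 <- ang$primary
  a3 <- ang$remote
  theta <- geometry$opm_angle_deg
  omega_o1 <- cone_solid_angle(a1)

  dirs <- fibonacci_directions(n_points, a1)
  ca3 <- cospi(a3 / 180)
  # secondary cone: coaxial with the primary axis
  in_o2 <- dirs[, 3] >= ca3
  # tertiary cone: axis tilted by theta in the xz plane
  ax <- c(sinpi(theta / 180), 0, cospi(theta / 180))
  in_o3 <- (dirs %*% ax)[, 1] >= ca3
  frac <- mean(in_o2 & in_o3)
  omega_opm <- omega_o1 * frac
  if (omega_opm == 0)
    warning("collection cones do not intersect; omega_opm is zero",
            call. = FALSE)

  nas <- suppressWarnings(effective_nas(geometry))
  structure(
    list(omega_opm = omega_opm, omega_o1 = omega_o1,
         latitudinal_na = nas$latitudinal_na,
         longitudinal_na = nas$longitudinal_na,
         view_separation_deg = view_separation(theta)),
    class = "aperture_report")
}

#' @export
print.aperture_report <- function(x, ...) {
  cat(sprintf(
    paste0("<aperture_report>\n  omega_opm  %.4g sr\n  omega_o1   %.4g sr",
           "\n  NA (lat)   %.2f\n  NA (long)  %.2f\n  views      %.4g deg apart\n"),
    x$omega_opm, x$omega_o1, round(x$latitudinal_na, 2),
    round(x$longitudinal_na, 2), x$view_separation_deg))
  invisible(x)
}

#' Transmission budget of the folded collection path
#'
#' The folded dOPM collection path loses light to (i) the double pass of the
#' secondary/tertiary objective and the polarizing beam splitter,
#' `t_optics = T_o23^2 * T_pbs`, and (ii) the ideal low-NA PBS double-pass
#' fluorescence transmission `t_pbs_fluo`, which is 0.50 for fully
#' depolarized emission from rapidly tumbling fluorophores (steady-state
#' anisotropy 0) and 0.75 for partially polarized emission from randomly
#' oriented static fluorophores excited by linearly polarized light
#' (anisotropy 0.4); see [pbs_lowna_transmission()].
#'
#' @param geometry A [system_geometry()].
#' @param regime `"tumbling"` or `"static"`.
#' @return Named list with `t_optics` and `t_pbs_fluo`.
#' @export
transmission_budget <- function(geometry, regime = c("tumbling", "static")) {
  stopifnot(inherits(geometry, "system_geometry"))
  regime <- match.arg(regime)
  t_o23 <- geometry$secondary_tertiary$single_pass_transmission
  list(
    t_optics = t_o23^2 * geometry$t_pbs,
    t_pbs_fluo = if (regime == "tumbling") 0.50 else 0.75)
}

#' Low-NA PBS double-pass transmission from emission anisotropy
#'
#' For paraxial (low-NA) detection along the optical axis with excitation
#' polarized along the PBS transmission axis, emission with steady-state
#' anisotropy `r` splits into parallel and perpendicular intensities with
#' `I_par / I_perp = (1 + 2 r) / (1 - r)`. The fraction of the transverse
#' intensity in the parallel (transmitted then returned) channel is
#' `(1 + 2 r) / (2 + r)`: 0.5 at `r = 0` (tumbling) and 0.75 at `r = 0.4`
#' (static random ensemble).
#'
#' @param anisotropy Steady-state fluorescence anisotropy, in `[-0.2, 0.4]`.
#' @return Transmitted fraction of the detected (transverse) intensity.
#' @export
pbs_lowna_transmission <- function(anisotropy) {
  stopifnot(is.numeric(anisotropy))
  if (any(anisotropy < -0.2 | anisotropy > 0.4))
    stop("steady-state anisotropy must lie in [-0.2, 0.4]")
  (1 + 2 * anisotropy) / (2 + anisotropy)
}

#' Geometric relative collection efficiency
#'
#' Relative collection efficiency (RCE) of the dOPM system with respect to
#' the primary objective alone, from the geometric (solid angle) model:
#' `RCE = (omega_opm / omega_o1) * t_optics * t_pbs_fluo`, where the solid
#' angle ratio comes from [intersection_solid_angle()] and the transmission
#' factors from [transmission_budget()].
#'
#' @inheritParams intersection_solid_angle
#' @inheritParams transmission_budget
#' @return RCE as a fraction in `[0, 1]`.
#' @examples
#' geometric_rce(dopm_geometry(35), "static", n_points = 1e5)
#' @export
geometric_rce <- function(geometry, regime = c("tumbling", "static"),
                          n_points = 1e6) {
  regime <- match.arg(regime)
  rep <- intersection_solid_angle(geometry, n_points = n_points)
  tb <- transmission_budget(geometry, regime)
  (rep$omega_opm / rep$omega_o1) * tb$t_optics * tb$t_pbs_fluo
}
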