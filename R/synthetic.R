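# Deterministic synthetic data generators: bead phantoms, dual-view
# oblique acquisitions, thin-sheet volumes and photobleaching series.
# All randomness is controlled by a mandatory seed; the noise model is
# Poisson photon noise plus optional Gaussian read noise, a reasonable
# first-order model of sCMOS detection.

#' Specification of a synthetic bead phantom
#'
#' @param size_um Volume extent, micrometres (length 1 or 3).
#' @param voxel_um Voxel size, micrometres (length 1 or 3).
#' @param n_beads Number of beads.
#' @param fwhm_um Bead image FWHM targets (x, y, z), micrometres; the
#'   defaults (0.29, 0.31, 0.83) mirror the measured resolution of the
#'   fused dual-view system at a 35 degree OPM angle. Must be at least two
#'   voxels for recovery tests to be meaningful.
#' @param tilt_deg Tilt of the PSF long axis in the y-z plane, degrees.
#' @param background Constant background level, photons.
#' @param peak_photons Expected peak signal per bead, photons.
#' @param read_noise_sd Gaussian read noise SD, photons (0 disables).
#' @param min_separation_um Minimum center-to-center bead distance.
#' @param seed Mandatory RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(size_um = 20, voxel_um = 0.1, n_beads = 30,
                         fwhm_um = c(0.29, 0.31, 0.83), tilt_deg = 0,
                         background = 10, peak_photons = 2000,
                         read_noise_sd = 2, min_separation_um = 3,
                         seed = 1L) {
  if (length(size_um) == 1L) size_um <- rep(size_um, 3)
  if (length(voxel_um) == 1L) voxel_um <- rep(voxel_um, 3)
  stopifnot(all(size_um > 0), all(voxel_um > 0), n_beads >= 0,
            length(fwhm_um) == 3, all(fwhm_um > 0), background >= 0,
            peak_photons >= 0, read_noise_sd >= 0)
  if (any(fwhm_um < 2 * voxel_um))
    warning("bead FWHM below 2 voxels on some axis; FWHM recovery will be ",
            "sampling-limited", call. = FALSE)
  structure(
    list(size_um = size_um, voxel_um = voxel_um, n_beads = n_beads,
         fwhm_um = fwhm_um, tilt_deg = tilt_deg, background = background,
         peak_photons = peak_photons, read_noise_sd = read_noise_sd,
         min_separation_um = min_separation_um, seed = as.integer(seed)),
    class = "phantom_spec")
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a bead phantom volume with ground truth
#'
#' Render sub-resolution beads at seeded-random, non-overlapping positions
#' as (optionally tilted) anisotropic Gaussian intensity profiles, add a
#' constant background, and apply Poisson photon noise plus Gaussian read
#' noise. Deterministic for a fixed spec (byte-identical volumes on
#' re-run).
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [lab_volume()]) and `truth` (data.frame
#'   of bead positions and programmed FWHMs).
#' @export
make_bead_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- pmax(1L, as.integer(round(spec$size_um / spec$voxel_um)) + 1L)
  margin <- pmax(1.5 * spec$fwhm_um, 0.5)
  lo <- margin
  hi <- spec$size_um - margin
  if (any(hi < lo) && spec$n_beads > 0)
    stop("volume too small for the requested bead margins")

  positions <- with_seed(spec$seed, {
    pos <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pos) < spec$n_beads) {
      cand <- c(stats::runif(1, lo[1], hi[1]),
                stats::runif(1, lo[2], hi[2]),
                stats::runif(1, lo[3], hi[3]))
      ok <- nrow(pos) == 0 ||
        min(sqrt(rowSums(sweep(pos, 2, cand)^2))) >= spec$min_separation_um
      if (ok) pos <- rbind(pos, cand)
      tries <- tries + 1L
      if (tries > 1000L * max(1L, spec$n_beads))
        stop("bead density too high to satisfy the minimum separation")
    }
    pos
  })

  sig <- spec$fwhm_um / (2 * sqrt(2 * log(2)))
  th <- spec$tilt_deg * pi / 180
  img <- array(0, dims)
  if (spec$n_beads > 0) {
    idx <- arrayInd(seq_len(prod(dims)), dims)
    xx <- (idx[, 1] - 1) * spec$voxel_um[1]
    yy <- (idx[, 2] - 1) * spec$voxel_um[2]
    zz <- (idx[, 3] - 1) * spec$voxel_um[3]
    acc <- numeric(prod(dims))
    for (b in seq_len(nrow(positions))) {
      dx <- xx - positions[b, 1]
      dy <- yy - positions[b, 2]
      dz <- zz - positions[b, 3]
      # rotate into the (possibly tilted) PSF frame: tilt in the y-z plane
      dy2 <- cos(th) * dy + sin(th) * dz
      dz2 <- -sin(th) * dy + cos(th) * dz
      # skip voxels far from the bead to keep rendering linear in n_beads
      near <- abs(dx) < 4 * sig[1] & abs(dy2) < 4 * sig[2] &
        abs(dz2) < 4 * sig[3]
      acc[near] <- acc[near] + spec$peak_photons *
        exp(-0.5 * (dx[near]^2 / sig[1]^2 + dy2[near]^2 / sig[2]^2 +
                      dz2[near]^2 / sig[3]^2))
    }
    img <- array(acc, dims)
  }
  expected <- img + spec$background
  noisy <- with_seed(spec$seed + 1L, {
    v <- stats::rpois(length(expected), lambda = expected)
    if (spec$read_noise_sd > 0)
      v <- v + stats::rnorm(length(expected), 0, spec$read_noise_sd)
    pmax(0, v)
  })
  truth <- if (spec$n_beads > 0)
    data.frame(x_um = positions[, 1], y_um = positions[, 2],
               z_um = positions[, 3],
               fwhm_x = spec$fwhm_um[1], fwhm_y = spec$fwhm_um[2],
               fwhm_z = spec$fwhm_um[3])
  else
    data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
               fwhm_x = numeric(), fwhm_y = numeric(), fwhm_z = numeric())
  list(volume = lab_volume(array(noisy, dims), spec$voxel_um), truth = truth)
}

#' Simulate a dual-view oblique acquisition of a lab-frame volume
#'
#' Apply the forward acquisition model ([forward_skew()]) for views 1 and 2
#' (opposite shear signs), optionally adding independent Poisson noise per
#' view.
#'
#' @param lab A [lab_volume()] ground-truth volume.
#' @param opm_angle_deg OPM angle, degrees.
#' @param scan_step_um,pixel_row_um,pixel_col_um Acquisition sampling;
#'   defaults follow the lab voxel size.
#' @param noise If `TRUE`, apply Poisson noise independently per view.
#' @param seed RNG seed (used only when `noise` is `TRUE`).
#' @return List with `view1` and `view2`, both [raw_oblique_stack()]s.
#' @export
make_oblique_acquisition <- function(lab, opm_angle_deg = 35,
                                     scan_step_um = NULL,
                                     pixel_row_um = NULL,
                                     pixel_col_um = NULL,
                                     noise = FALSE, seed = 1L) {
  stopifnot(inherits(lab, "lab_volume"))
  if (is.null(scan_step_um)) scan_step_um <- lab$voxel_size_um[2]
  if (is.null(pixel_row_um)) pixel_row_um <- lab$voxel_size_um[3]
  if (is.null(pixel_col_um)) pixel_col_um <- lab$voxel_size_um[1]
  views <- lapply(1:2, function(v)
    forward_skew(lab, scan_step_um, pixel_row_um, pixel_col_um,
                 opm_angle_deg, v))
  if (noise) {
    views <- with_seed(seed, lapply(views, function(st) {
      st$voxels <- array(stats::rpois(length(st$voxels), st$voxels),
                         dim(st$voxels))
      st
    }))
  }
  list(view1 = views[[1]], view2 = views[[2]])
}

#' Synthetic thin fluorescent sheet volume
#'
#' Single plane with a Gaussian axial intensity profile spanning the full
#' lateral field of view, optionally tilted about the x axis, with optional
#' Poisson noise: the phantom used to measure system optical sectioning.
#'
#' @param fwhm_um Axial FWHM of the sheet, micrometres.
#' @param tilt_deg Tilt of the sheet plane about the x axis, degrees.
#' @param size_um Volume extent (length 1 or 3), micrometres.
#' @param voxel_um Voxel size (length 1 or 3), micrometres.
#' @param peak_photons Peak sheet intensity, photons.
#' @param noise If `TRUE`, apply Poisson noise.
#' @param seed RNG seed (used when `noise` is `TRUE`).
#' @return A [lab_volume()] with the sheet centered axially.
#' @export
make_sheet_phantom <- function(fwhm_um = 3, tilt_deg = 0,
                               size_um = c(10, 10, 20), voxel_um = 0.25,
                               peak_photons = 1000, noise = FALSE,
                               seed = 1L) {
  stopifnot(fwhm_um > 0)
  if (length(size_um) == 1L) size_um <- rep(size_um, 3)
  if (length(voxel_um) == 1L) voxel_um <- rep(voxel_um, 3)
  dims <- pmax(1L, as.integer(round(size_um / voxel_um)) + 1L)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  yy <- (idx[, 2] - 1) * voxel_um[2]
  zz <- (idx[, 3] - 1) * voxel_um[3]
  z0 <- size_um[3] / 2 + tanpi(tilt_deg / 180) * (yy - size_um[2] / 2)
  img <- peak_photons * exp(-4 * log(2) * (zz - z0)^2 / fwhm_um^2)
  if (noise)
    img <- with_seed(seed, stats::rpois(length(img), img))
  lab_volume(array(img, dims), voxel_um)
}

#' Synthetic photobleaching time series
#'
#' Per-ROI exponentially decaying intensities
#' `I(t) = I0 exp(-k t)` with optional Gaussian noise, over `n_timepoints`
#' unit-spaced frames starting at `t = 0`.
#'
#' @param rates Vector of decay rates `k >= 0` (one ROI per rate), in
#'   inverse frame units.
#' @param n_timepoints Number of frames (`>= 2`).
#' @param i0 Initial intensity (scalar or one per ROI).
#' @param noise_sd Gaussian noise SD (0 disables).
#' @param seed RNG seed.
#' @return Matrix (time points x ROIs).
#' @export
make_bleach_series <- function(rates, n_timepoints = 50, i0 = 1000,
                               noise_sd = 0, seed = 1L) {
  stopifnot(all(rates >= 0), n_timepoints >= 2)
  t <- seq_len(n_timepoints) - 1
  base <- outer(t, rates, function(tt, k) exp(-k * tt))
  base <- sweep(base, 2, rep_len(i0, length(rates)), "*")
  if (noise_sd > 0)
    base <- with_seed(seed,
      base + matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base)))
  base
}
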