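# Bead and thin-sheet metrology: PSF FWHM, optical sectioning, summary
# statistics, relative collection efficiency and photobleaching statistics.

gauss_fwhm_factor <- 2 * sqrt(2 * log(2))  # FWHM = 2.3548 sigma

# 1D Gaussian fit y ~ b + A exp(-(x - mu)^2 / (2 sigma^2)).
# Moment-based start, refined by nls; returns NULL on failure.
fit_gaussian_1d <- function(x, y) {
  b0 <- min(y)
  yc <- pmax(0, y - b0)
  if (sum(yc) <= 0) return(NULL)
  mu0 <- sum(x * yc) / sum(yc)
  s0 <- sqrt(pmax(1e-12, sum((x - mu0)^2 * yc) / sum(yc)))
  a0 <- max(y) - b0
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ b + a * exp(-(x - mu)^2 / (2 * sg^2)),
                 start = list(b = b0, a = a0, mu = mu0, sg = s0),
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["a"]] <= 0) return(NULL)
  res <- stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  list(background = cf[["b"]], amplitude = cf[["a"]], mu = cf[["mu"]],
       sigma = abs(cf[["sg"]]), fwhm = gauss_fwhm_factor * abs(cf[["sg"]]),
       r2 = r2)
}

#' Detect isolated bead candidates in a volume
#'
#' Find local intensity maxima above a signal-to-noise threshold, exclude
#' candidates near the volume border, and prune pairs closer than a
#' minimum separation (both members are excluded as "crowded", since
#' overlapping bead images bias the fits).
#'
#' @param volume A [lab_volume()].
#' @param min_separation_um Minimum allowed distance between candidates,
#'   micrometres (default 3).
#' @param snr_threshold Required peak height above background in units of
#'   the background noise SD (default 8; million-voxel volumes produce
#'   spurious local maxima well past 5 SD in the Poisson tail).
#' @param border_um Exclusion margin from the volume border, micrometres
#'   (default 1).
#' @return A data.frame with voxel indices (`ix, iy, iz`), lab positions
#'   (`x_um, y_um, z_um`), peak `intensity`, `included` flag and exclusion
#'   `reason` (empty detections give a zero-row data.frame).
#' @export
detect_beads <- function(volume, min_separation_um = 3, snr_threshold = 8,
                         border_um = 1) {
  stopifnot(inherits(volume, "lab_volume"))
  a <- volume$voxels
  d <- dim(a)
  bg <- stats::median(a)
  noise <- stats::mad(a)
  if (noise == 0) noise <- stats::sd(a)
  if (is.na(noise) || noise == 0) noise <- 1
  thr <- bg + snr_threshold * noise

  # local maxima over the 26-neighborhood, computed by array shifts
  is_max <- a >= thr
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (!any(is_max)) break
    sh <- array(-Inf, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    sh[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
    is_max <- is_max & (a >= sh)
  }
  idx <- which(is_max)
  if (length(idx) == 0)
    return(data.frame(ix = integer(), iy = integer(), iz = integer(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      intensity = numeric(), included = logical(),
                      reason = character()))
  pos <- arrayInd(idx, d)
  out <- data.frame(
    ix = pos[, 1], iy = pos[, 2], iz = pos[, 3],
    x_um = volume$origin_um[1] + (pos[, 1] - 1) * volume$voxel_size_um[1],
    y_um = volume$origin_um[2] + (pos[, 2] - 1) * volume$voxel_size_um[2],
    z_um = volume$origin_um[3] + (pos[, 3] - 1) * volume$voxel_size_um[3],
    intensity = a[idx], included = TRUE, reason = "",
    stringsAsFactors = FALSE)

  # border exclusion
  lim_lo <- volume$origin_um + border_um
  lim_hi <- volume$origin_um + (d - 1) * volume$voxel_size_um - border_um
  at_border <- out$x_um < lim_lo[1] | out$x_um > lim_hi[1] |
    out$y_um < lim_lo[2] | out$y_um > lim_hi[2] |
    out$z_um < lim_lo[3] | out$z_um > lim_hi[3]
  out$included[at_border] <- FALSE
  out$reason[at_border] <- "border"

  # crowding: any pair closer than min_separation excludes both
  if (nrow(out) > 1) {
    dm <- as.matrix(stats::dist(out[, c("x_um", "y_um", "z_um")]))
    diag(dm) <- Inf
    crowded <- apply(dm, 1, min) < min_separation_um
    out$included[crowded] <- FALSE
    out$reason[crowded] <- ifelse(out$reason[crowded] == "", "crowded",
                                  out$reason[crowded])
  }
  out
}

# extract a sub-volume around a voxel index, clipped at the borders
extract_subvolume <- function(volume, center_idx, half_um) {
  d <- dim(volume$voxels)
  half <- pmax(1L, as.integer(ceiling(half_um / volume$voxel_size_um)))
  lo <- pmax(1L, center_idx - half)
  hi <- pmin(d, center_idx + half)
  sub <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab_volume(sub, volume$voxel_size_um,
             volume$origin_um + (lo - 1) * volume$voxel_size_um)
}

# median of the outermost voxel shell: robust local background
shell_background <- function(arr) {
  d <- dim(arr)
  inner <- arr
  if (all(d > 2)) inner <- arr[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  total <- sum(arr); n_in <- length(inner)
  shell_vals <- c(arr[c(1, d[1]), , ], arr[, c(1, d[2]), ], arr[, , c(1, d[3])])
  stats::median(shell_vals)
}

#' Measure bead image FWHM along the three axes
#'
#' Fits 1D Gaussians to the axis-aligned intensity profiles through the
#' sub-voxel centroid of a background-subtracted bead sub-volume, and
#' reports the FWHM (`2 sqrt(2 ln 2) sigma`) per axis in micrometres.
#'
#' @param subvolume A [lab_volume()] containing a single bead.
#' @param r2_threshold Minimum per-axis goodness of fit for inclusion
#'   (default 0.9).
#' @return A list with `fwhm_um` (length 3), `sigma_um`, `r2` (per axis),
#'   `centroid_um`, and `included` (FALSE with a `reason` when any fit
#'   fails or falls below the threshold).
#' @export
measure_fwhm <- function(subvolume, r2_threshold = 0.9) {
  stopifnot(inherits(subvolume, "lab_volume"))
  a <- subvolume$voxels
  bg <- shell_background(a)
  ac <- a - bg
  ac[ac < 0] <- 0
  d <- dim(a)
  if (sum(ac) <= 0)
    return(list(fwhm_um = rep(NA_real_, 3), sigma_um = rep(NA_real_, 3),
                r2 = rep(NA_real_, 3), centroid_um = rep(NA_real_, 3),
                included = FALSE, reason = "no signal"))
  # sub-voxel centroid (zero-based fractional indices)
  gx <- apply(ac, 1, sum); gy <- apply(ac, 2, sum); gz <- apply(ac, 3, sum)
  cen <- c(sum((seq_len(d[1]) - 1) * gx) / sum(gx),
           sum((seq_len(d[2]) - 1) * gy) / sum(gy),
           sum((seq_len(d[3]) - 1) * gz) / sum(gz))

  fwhm <- sigma <- r2 <- rep(NA_real_, 3)
  for (ax in 1:3) {
    n <- d[ax]
    t <- seq_len(n) - 1
    oth <- setdiff(1:3, ax)
    f <- matrix(0, n, 3)
    f[, ax] <- t
    f[, oth[1]] <- cen[oth[1]]
    f[, oth[2]] <- cen[oth[2]]
    prof <- trilinear_sample(a, f[, 1], f[, 2], f[, 3])
    fit <- fit_gaussian_1d(t * subvolume$voxel_size_um[ax], prof)
    if (!is.null(fit)) {
      fwhm[ax] <- fit$fwhm; sigma[ax] <- fit$sigma; r2[ax] <- fit$r2
    }
  }
  centroid_um <- subvolume$origin_um + cen * subvolume$voxel_size_um
  ok <- all(is.finite(fwhm)) && all(r2 >= r2_threshold)
  list(fwhm_um = fwhm, sigma_um = sigma, r2 = r2,
       centroid_um = centroid_um, included = ok,
       reason = if (ok) "" else "fit")
}

#' Optical sectioning strength from a single bead
#'
#' Axial profile of the laterally integrated bead signal: the background
#' subtracted sub-volume is summed over x and y per z plane and the FWHM of
#' the resulting profile is measured by half-maximum crossings with linear
#' interpolation. Because the lateral integration window is finite, energy
#' that defocus spreads beyond it is lost, so this reads wider than the
#' bead axial FWHM for realistic PSFs.
#'
#' @param subvolume A [lab_volume()] around one bead, with generous
#'   lateral margins.
#' @return List with `fwhm_um`, the axial `profile`, `z_um`, and
#'   `included` (FALSE with `reason` when the profile has no half-maximum
#'   crossing on both sides, e.g. for flat non-sectioned profiles).
#' @export
bead_sectioning <- function(subvolume) {
  stopifnot(inherits(subvolume, "lab_volume"))
  a <- subvolume$voxels
  bg <- shell_background(a)
  ac <- a - bg
  ac[ac < 0] <- 0
  prof <- apply(ac, 3, sum)
  z <- (seq_along(prof) - 1) * subvolume$voxel_size_um[3]
  if (max(prof) <= 0 || (max(prof) - min(prof)) < 1e-9 * max(prof, 1))
    return(list(fwhm_um = NA_real_, profile = prof, z_um = z,
                included = FALSE, reason = "flat profile"))
  pk <- which.max(prof)
  half <- prof[pk] / 2
  left <- right <- NA_real_
  if (pk > 1) {
    lo <- which(prof[1:(pk - 1)] < half)
    if (length(lo)) {
      i <- max(lo)
      left <- z[i] + (half - prof[i]) / (prof[i + 1] - prof[i]) *
        (z[i + 1] - z[i])
    }
  }
  if (pk < length(prof)) {
    hii <- which(prof[(pk + 1):length(prof)] < half) + pk
    if (length(hii)) {
      i <- min(hii)
      right <- z[i - 1] + (prof[i - 1] - half) / (prof[i - 1] - prof[i]) *
        (z[i] - z[i - 1])
    }
  }
  if (!is.finite(left) || !is.finite(right))
    return(list(fwhm_um = NA_real_, profile = prof, z_um = z,
                included = FALSE, reason = "no half-max crossing"))
  list(fwhm_um = right - left, profile = prof, z_um = z, included = TRUE,
       reason = "")
}

#' Optical sectioning map from a thin fluorescent sheet volume
#'
#' Fits a 1D Gaussian to the axial profile of every lateral (x, y) column
#' of a thin-sheet volume and returns the per-column FWHM map with its
#' median / IQR / 95 percent CI summary. Columns without a usable peak are
#' masked (NA).
#'
#' @param sheet_volume A [lab_volume()] of a thin fluorescent plane.
#' @param r2_threshold Minimum column fit quality (default 0.8).
#' @param stride Fit every `stride`-th column in x and y (default 1) to
#'   bound runtime on large volumes.
#' @return List with `fwhm_map_um` (matrix, NA where masked) and `summary`
#'   (a [summarize_records()] result over the unmasked columns).
#' @export
sheet_sectioning <- function(sheet_volume, r2_threshold = 0.8, stride = 1L) {
  stopifnot(inherits(sheet_volume, "lab_volume"))
  a <- sheet_volume$voxels
  d <- dim(a)
  z <- (seq_len(d[3]) - 1) * sheet_volume$voxel_size_um[3]
  xs <- seq(1L, d[1], by = stride)
  ys <- seq(1L, d[2], by = stride)
  fw <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    prof <- a[xs[i], ys[j], ]
    fit <- fit_gaussian_1d(z, prof)
    if (!is.null(fit) && fit$r2 >= r2_threshold &&
        fit$fwhm >= sheet_volume$voxel_size_um[3])
      fw[i, j] <- fit$fwhm
  }
  vals <- fw[is.finite(fw)]
  list(fwhm_map_um = fw,
       summary = if (length(vals)) summarize_records(vals) else NULL)
}

#' Median, IQR and distribution-free 95 percent CI of a metric
#'
#' Summarizes per-bead (or per-column) measurements the way resolution
#' tables report them: median, interquartile range and a 95 percent
#' confidence interval on the median from binomial order statistics
#' (distribution-free, deterministic: ranks `qbinom(0.025, n, 0.5)` and
#' `n + 1 - qbinom(0.025, n, 0.5)` of the sorted sample, clamped to the
#' data range for small n).
#'
#' @param values Numeric vector of included measurements (length `>= 1`).
#' @return List with `n`, `median`, `iqr`, `ci95` (length 2).
#' @export
summarize_records <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("no included records to summarize")
  n <- length(values)
  s <- sort(values)
  lo_rank <- max(1L, stats::qbinom(0.025, n, 0.5))
  hi_rank <- min(n, n + 1L - lo_rank)
  list(n = n, median = stats::median(values),
       iqr = stats::IQR(values),
       ci95 = c(s[lo_rank], s[hi_rank]))
}

#' Summarize a table of per-bead FWHM records
#'
#' Applies [summarize_records()] to each FWHM column of a bead-record
#' data.frame (as produced by [measure_beads()]), restricted to included
#' beads, and adds a z-binned median profile of the axial FWHM.
#'
#' @param records data.frame with columns `fwhm_x`, `fwhm_y`, `fwhm_z`
#'   (and optionally `sectioning_fwhm`, `z_um`, `included`).
#' @param z_bin_um Bin width for the z profile (default 10).
#' @return List of per-metric summaries (class `bead_summary`).
#' @export
summarize_beads <- function(records, z_bin_um = 10) {
  stopifnot(is.data.frame(records))
  if ("included" %in% names(records)) records <- records[records$included, ]
  if (nrow(records) < 1) stop("no included records to summarize")
  metrics <- intersect(c("fwhm_x", "fwhm_y", "fwhm_z", "sectioning_fwhm"),
                       names(records))
  out <- lapply(metrics, function(m) summarize_records(records[[m]]))
  names(out) <- metrics
  if (all(c("z_um", "fwhm_z") %in% names(records))) {
    bins <- floor(records$z_um / z_bin_um)
    prof <- tapply(records$fwhm_z, bins, stats::median)
    out$z_profile <- data.frame(z_bin_um = as.numeric(names(prof)) * z_bin_um,
                                median_fwhm_z = as.numeric(prof))
  }
  structure(out, class = "bead_summary")
}

#' Percentage change between two medians
#'
#' `100 * (b / a - 1)`: the percent change of `b` relative to `a`, as used
#' to compare resolution medians between configurations (e.g. the x FWHM
#' medians 0.293 and 0.301 um give +2.7 percent).
#'
#' @param median_a Reference median (`> 0`).
#' @param median_b Comparison median (`> 0`).
#' @return Percent change (positive when `b > a`).
#' @export
percent_change <- function(median_a, median_b) {
  stopifnot(is.numeric(median_a), is.numeric(median_b))
  if (any(median_a <= 0) || any(median_b <= 0))
    stop("medians must be positive")
  100 * (median_b / median_a - 1)
}

#' Full bead metrology over a volume
#'
#' Convenience pipeline: detect beads, then measure per-axis FWHM and
#' sectioning strength for each isolated candidate, applying the inclusion
#' criteria (per-axis fit r^2, border margin, neighbor separation).
#'
#' @param volume A [lab_volume()].
#' @param fit_half_um Half-size of the fitting sub-volume, micrometres
#'   (length 1 or 3; default `c(1, 1, 3)`).
#' @param sectioning_half_um Half-size of the (laterally wider) sectioning
#'   sub-volume (default `c(2.5, 2.5, 5)`).
#' @inheritParams detect_beads
#' @inheritParams measure_fwhm
#' @return data.frame of bead records: positions, `fwhm_x/y/z`,
#'   `sectioning_fwhm`, per-axis `r2_*`, `included`, `reason`.
#' @export
measure_beads <- function(volume, min_separation_um = 3, snr_threshold = 8,
                          border_um = 1, fit_half_um = c(1, 1, 3),
                          sectioning_half_um = c(2.5, 2.5, 5),
                          r2_threshold = 0.9) {
  cand <- detect_beads(volume, min_separation_um, snr_threshold, border_um)
  if (length(fit_half_um) == 1L) fit_half_um <- rep(fit_half_um, 3)
  if (length(sectioning_half_um) == 1L)
    sectioning_half_um <- rep(sectioning_half_um, 3)
  n <- nrow(cand)
  res <- data.frame(
    x_um = cand$x_um, y_um = cand$y_um, z_um = cand$z_um,
    fwhm_x = NA_real_, fwhm_y = NA_real_, fwhm_z = NA_real_,
    sectioning_fwhm = NA_real_,
    r2_x = NA_real_, r2_y = NA_real_, r2_z = NA_real_,
    included = cand$included, reason = cand$reason,
    stringsAsFactors = FALSE)
  for (b in seq_len(n)) {
    if (!cand$included[b]) next
    ctr <- c(cand$ix[b], cand$iy[b], cand$iz[b])
    m <- measure_fwhm(extract_subvolume(volume, ctr, fit_half_um),
                      r2_threshold)
    res$fwhm_x[b] <- m$fwhm_um[1]
    res$fwhm_y[b] <- m$fwhm_um[2]
    res$fwhm_z[b] <- m$fwhm_um[3]
    res$r2_x[b] <- m$r2[1]; res$r2_y[b] <- m$r2[2]; res$r2_z[b] <- m$r2[3]
    if (!m$included) {
      res$included[b] <- FALSE
      res$reason[b] <- m$reason
      next
    }
    sec <- bead_sectioning(extract_subvolume(volume, ctr,
                                             sectioning_half_um))
    res$sectioning_fwhm[b] <- sec$fwhm_um
  }
  res
}

#' 99 percent encircled-energy radius of an Airy pattern
#'
#' Radius (in units of the optical coordinate `v = 2 pi NA r / lambda`, or
#' in micrometres when `wavelength_nm` and `na` are supplied) enclosing a
#' given fraction of the total energy of an Airy diffraction pattern, using
#' the closed form `EE(v) = 1 - J0(v)^2 - J1(v)^2`.
#'
#' @param fraction Enclosed-energy fraction, in `(0, 1)` (default 0.99).
#' @param wavelength_nm,na Optional wavelength (nm) and numerical aperture;
#'   when given, the radius is returned in micrometres.
#' @return The radius (optical units, or micrometres).
#' @export
airy_encircled_radius <- function(fraction = 0.99, wavelength_nm = NULL,
                                  na = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  ee <- function(v) 1 - besselJ(v, 0)^2 - besselJ(v, 1)^2
  v <- stats::uniroot(function(v) ee(v) - fraction, c(1e-6, 2000),
                      tol = 1e-10)$root
  if (!is.null(wavelength_nm) && !is.null(na))
    v * (wavelength_nm * 1e-3) / (2 * pi * na)
  else v
}

#' Relative collection efficiency from an epi / light-sheet image pair
#'
#' Implements the background-corrected signal ratio
#' `eta = (S_dopm - B_dopm) / (S_epi - B_epi)` for a single isolated bead
#' imaged by both detection paths: the signal ROI is a square centered on
#' the bead sized to enclose at least 99 percent of the bead energy
#' (computed from the Airy encircled-energy radius at the given wavelength
#' and NA), and the background ROI is an adjacent square of equal size.
#'
#' @param epi_image,dopm_image 2D matrices (same pixel size) containing the
#'   same isolated bead.
#' @param bead_center Length-2 pixel indices (x, y) of the bead.
#' @param pixel_um Image pixel size, micrometres.
#' @param wavelength_nm Emission wavelength, nm.
#' @param na Collection NA used for the ROI size.
#' @return Object of class `relative_efficiency`: list with `eta`,
#'   `s_dopm`, `b_dopm`, `s_epi`, `b_epi`, `roi_half_px`.
#' @export
relative_efficiency <- function(epi_image, dopm_image, bead_center,
                                pixel_um, wavelength_nm = 520, na = 1.2) {
  stopifnot(is.matrix(epi_image), is.matrix(dopm_image),
            length(bead_center) == 2, pixel_um > 0)
  r_um <- airy_encircled_radius(0.99, wavelength_nm, na)
  half <- max(1L, as.integer(ceiling(r_um / pixel_um)))
  d <- dim(epi_image)
  cx <- round(bead_center[1]); cy <- round(bead_center[2])
  fits <- function(x, y) x - half >= 1 && x + half <= d[1] &&
    y - half >= 1 && y + half <= d[2]
  if (!fits(cx, cy))
    stop("image too small for the 99% encircled-energy signal ROI")
  sq <- function(img, x, y)
    sum(img[(x - half):(x + half), (y - half):(y + half)])
  # adjacent equal-size background ROI: first side (x+, x-, y+, y-) that
  # fits fully inside the image
  off <- 2L * half + 1L
  cand <- list(c(cx + off, cy), c(cx - off, cy),
               c(cx, cy + off), c(cx, cy - off))
  ok <- vapply(cand, function(p) fits(p[1], p[2]), logical(1))
  if (!any(ok))
    stop("image too small for an adjacent equal-size background ROI")
  bpos <- cand[[which(ok)[1]]]
  s_epi <- sq(epi_image, cx, cy)
  b_epi <- sq(epi_image, bpos[1], bpos[2])
  s_dopm <- sq(dopm_image, cx, cy)
  b_dopm <- sq(dopm_image, bpos[1], bpos[2])
  if (s_epi <= b_epi)
    stop("epi signal does not exceed background; eta undefined")
  structure(
    list(eta = (s_dopm - b_dopm) / (s_epi - b_epi),
         s_dopm = s_dopm, b_dopm = b_dopm, s_epi = s_epi, b_epi = b_epi,
         roi_half_px = half),
    class = "relative_efficiency")
}

#' Photobleaching statistics from ROI time series
#'
#' Per-ROI percentage signal drop over an experiment,
#' `100 * (1 - I_end / I_start)`, with robust start and end estimates
#' (means of the first and last `k` frames), summarized as median and IQR
#' across ROIs.
#'
#' @param timeseries_rois Numeric matrix (time points x ROIs) or vector
#'   (single ROI).
#' @param k Number of frames averaged at each end (default 3, clamped to
#'   half the series length).
#' @return List with `percent_drop` (per ROI), `median`, `iqr`.
#' @export
photobleach_stats <- function(timeseries_rois, k = 3L) {
  if (is.vector(timeseries_rois))
    timeseries_rois <- matrix(timeseries_rois, ncol = 1)
  stopifnot(is.matrix(timeseries_rois))
  nt <- nrow(timeseries_rois)
  if (nt < 2) stop("need at least 2 timepoints")
  k <- max(1L, min(as.integer(k), nt %/% 2L))
  start <- colMeans(timeseries_rois[seq_len(k), , drop = FALSE])
  end <- colMeans(timeseries_rois[(nt - k + 1):nt, , drop = FALSE])
  drop_pct <- 100 * (1 - end / start)
  list(percent_drop = drop_pct,
       median = stats::median(drop_pct),
       iqr = stats::IQR(drop_pct))
}
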