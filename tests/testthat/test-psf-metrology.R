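# Bead/sheet metrology, summary statistics, relative efficiency and
# photobleaching statistics.

make_gaussian_bead <- function(sigma_um = c(0.124, 0.124, 0.124),
                               voxel_um = 0.04, half_um = 1,
                               background = 0, peak = 1000) {
  n <- 2 * ceiling(half_um / voxel_um) + 1
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_um
  gx <- exp(-ax^2 / (2 * sigma_um[1]^2))
  gy <- exp(-ax^2 / (2 * sigma_um[2]^2))
  gz <- exp(-ax^2 / (2 * sigma_um[3]^2))
  vol <- peak * outer(outer(gx, gy), gz) + background
  lab_volume(array(vol, c(n, n, n)), voxel_um)
}

test_that("bead detection: phantom recovery, empty input, crowding rule", {
  spec <- phantom_spec(size_um = c(20, 20, 20), voxel_um = 0.2, n_beads = 25,
                       fwhm_um = c(0.6, 0.6, 1.2), seed = 21,
                       min_separation_um = 4)
  ph <- make_bead_phantom(spec)
  det <- detect_beads(ph$volume, min_separation_um = 3)
  found <- det[det$included, ]
  expect_equal(nrow(found), 25)
  # each detection within one voxel of a true bead
  for (b in seq_len(nrow(found))) {
    dmin <- min(sqrt((ph$truth$x_um - found$x_um[b])^2 +
                     (ph$truth$y_um - found$y_um[b])^2 +
                     (ph$truth$z_um - found$z_um[b])^2))
    expect_lt(dmin, sqrt(3) * 0.2 + 1e-9)
  }

  # uniform background: nothing detected
  flat <- lab_volume(array(10, c(20, 20, 20)), 0.5)
  expect_equal(nrow(detect_beads(flat)[detect_beads(flat)$included, ]), 0)

  # two beads closer than min_separation are both excluded as crowded
  a <- array(0, c(30, 30, 30))
  a[10, 15, 15] <- 100; a[14, 15, 15] <- 100
  vol <- lab_volume(a, 0.5)   # beads 2 um apart
  det2 <- detect_beads(vol, min_separation_um = 3, border_um = 1)
  expect_true(all(!det2$included))
  expect_true(all(det2$reason == "crowded"))
})

test_that("FWHM measurement: absolute scale, symmetry, anisotropy ratio", {
  # isotropic sigma = 0.124 um -> FWHM = 2.3548 sigma = 0.292 um
  bead <- make_gaussian_bead(sigma_um = rep(0.124, 3))
  m <- measure_fwhm(bead)
  expect_true(m$included)
  expect_equal(m$fwhm_um, rep(2 * sqrt(2 * log(2)) * 0.124, 3),
               tolerance = 0.02)
  expect_equal(m$fwhm_um[1], m$fwhm_um[2], tolerance = 1e-6)

  # programmed anisotropy sigma_z / sigma_x = 2.8 recovered within 5%
  bead2 <- make_gaussian_bead(sigma_um = c(0.1, 0.1, 0.28), half_um = 1.6)
  m2 <- measure_fwhm(bead2)
  expect_equal(m2$fwhm_um[3] / m2$fwhm_um[1], 2.8, tolerance = 0.05)
})

test_that("FWHM estimator is unbiased within 2% for noisy sampled beads", {
  # >= 4 voxels per FWHM, Poisson noise at peak SNR >= 10
  sig <- 0.2                  # FWHM 0.471 um at voxel 0.1 -> 4.7 voxels
  set.seed(9)
  errs <- vapply(1:5, function(i) {
    bead <- make_gaussian_bead(sigma_um = rep(sig, 3), voxel_um = 0.1,
                               half_um = 1.2, background = 5, peak = 400)
    noisy <- lab_volume(array(rpois(length(bead$voxels), bead$voxels),
                              dim(bead$voxels)), bead$voxel_size_um)
    measure_fwhm(noisy)$fwhm_um[1]
  }, numeric(1))
  expect_equal(mean(errs), 2 * sqrt(2 * log(2)) * sig, tolerance = 0.02)
})

test_that("bead sectioning: separable, defocus-spread and flat profiles", {
  bead <- make_gaussian_bead(sigma_um = c(0.15, 0.15, 0.4), half_um = 2)
  sec <- bead_sectioning(bead)
  m <- measure_fwhm(bead)
  expect_true(sec$included)
  # separable Gaussian: sectioning FWHM equals the axial FWHM
  expect_equal(sec$fwhm_um, m$fwhm_um[3], tolerance = 0.05)

  # defocus-like energy spread: constant per-plane energy with lateral
  # sigma growing in |z| reads wider than the axial point FWHM because the
  # finite window loses defocused energy
  n <- 41; voxel <- 0.1
  ax <- (seq_len(n) - 21) * voxel
  vol <- array(0, c(n, n, n))
  sz <- 0.4
  for (k in seq_len(n)) {
    s_lat <- 0.15 * (1 + (abs(ax[k]) / 0.5)^2)
    plane_energy <- exp(-ax[k]^2 / (2 * sz^2))
    g <- exp(-ax^2 / (2 * s_lat^2))
    g2 <- outer(g, g); g2 <- g2 / sum(g2)
    vol[, , k] <- 1e4 * plane_energy * g2
  }
  lv <- lab_volume(vol, voxel)
  sec2 <- bead_sectioning(lv)
  ax_fwhm <- measure_fwhm(lv)$fwhm_um[3]
  expect_gt(sec2$fwhm_um, ax_fwhm)

  # flat profile: excluded
  flat <- lab_volume(array(5, c(9, 9, 9)), 0.5)
  expect_false(bead_sectioning(flat)$included)
})

test_that("sheet sectioning: recovery, tilt invariance, sampling floor", {
  sheet <- make_sheet_phantom(3.0, size_um = c(4, 4, 16), voxel_um = 0.25)
  s <- sheet_sectioning(sheet, stride = 4)
  expect_equal(s$summary$median, 3.0, tolerance = 0.02)

  tilted <- make_sheet_phantom(3.0, tilt_deg = 10, size_um = c(4, 4, 16),
                               voxel_um = 0.25)
  st <- sheet_sectioning(tilted, stride = 4)
  # per-column fits are about each column's own peak: tilt leaves the map
  # unchanged
  expect_equal(st$summary$median, s$summary$median, tolerance = 0.02)

  # near-zero thickness: FWHM is floored by the axial voxel size
  thin <- make_sheet_phantom(0.05, size_um = c(2, 2, 8), voxel_um = 0.25)
  sth <- sheet_sectioning(thin, stride = 4)
  if (!is.null(sth$summary))
    expect_gte(sth$summary$median, 0.25)
})

test_that("summaries: sort-based oracle, permutation invariance, CI", {
  set.seed(3)
  x <- rlnorm(101, 0, 0.3)
  s <- summarize_records(x)
  xs <- sort(x)
  expect_equal(s$median, xs[51])
  expect_equal(s$iqr, IQR(x))
  expect_equal(summarize_records(sample(x))$ci95, s$ci95)
  expect_true(s$ci95[1] <= s$median && s$median <= s$ci95[2])
  expect_error(summarize_records(numeric(0)), "no included")
})

test_that("median CI has ~95% coverage on simulated ensembles", {
  set.seed(17)
  n <- 31
  true_med <- qlnorm(0.5, 0, 0.5)
  hits <- vapply(seq_len(1000), function(i) {
    x <- rlnorm(n, 0, 0.5)
    ci <- summarize_records(x)$ci95
    ci[1] <= true_med && true_med <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.99)
})

test_that("percent change matches the printed-median arithmetic", {
  expect_equal(round(percent_change(0.293, 0.301), 1), 2.7)
  expect_equal(percent_change(1.7, 1.7), 0)
  expect_error(percent_change(0, 1), "positive")
})

test_that("Airy ROI radius matches a quadrature oracle", {
  # encircled energy by numerical integration of the Airy intensity
  # total energy of the Airy pattern in these units is 2, hence the 1/2
  ee_num <- function(v)
    0.5 * stats::integrate(function(u) (2 * besselJ(u, 1) / u)^2 * u,
                           1e-9, v, rel.tol = 1e-10)$value
  v99 <- airy_encircled_radius(0.99)
  expect_equal(ee_num(v99), 0.99, tolerance = 1e-3)
  # unit conversion
  r_um <- airy_encircled_radius(0.99, wavelength_nm = 520, na = 1.2)
  expect_equal(r_um, v99 * 0.520 / (2 * pi * 1.2), tolerance = 1e-12)
})

test_that("relative efficiency: constructed ratio, identity, offsets", {
  # synthetic epi / light-sheet pair differing by a known amplitude factor
  # the 99% Airy radius at NA 1.2 / 520 nm is ~4.4 um, so the image must
  # fit a 44-px-half signal ROI plus an adjacent background ROI
  axx <- seq(-15, 15, by = 0.1)
  axy <- seq(-5, 5, by = 0.1)
  psf <- exp(-outer(axx^2, axy^2, "+") / (2 * 0.3^2))
  ctr <- c(which(axx == 0), which(axy == 0))
  epi <- 1000 * psf + 50
  dopm <- 230 * psf + 50
  m <- relative_efficiency(epi, dopm, bead_center = ctr,
                           pixel_um = 0.1, wavelength_nm = 520, na = 1.2)
  expect_equal(m$eta, 0.23, tolerance = 0.02)

  ident <- relative_efficiency(epi, epi, ctr, 0.1)
  expect_equal(ident$eta, 1)

  # invariant to a constant offset added to both images
  m2 <- relative_efficiency(epi + 500, dopm + 500, ctr, 0.1)
  expect_equal(m2$eta, m$eta, tolerance = 1e-9)

  expect_error(relative_efficiency(matrix(1, 50, 50), matrix(1, 50, 50),
                                   c(25, 25), 0.1),
               "ROI")
})

test_that("photobleaching statistics", {
  # exponential decay to half over the series
  nt <- 101
  half <- make_bleach_series(log(2) / (nt - 1), n_timepoints = nt)
  st <- photobleach_stats(half, k = 1)
  expect_equal(st$median, 50, tolerance = 1e-6)

  flat <- make_bleach_series(0, n_timepoints = 20)
  expect_equal(photobleach_stats(flat)$median, 0)

  # noisy ensemble with known rates: median drop within 2% of analytic
  rates <- seq(0.005, 0.02, length.out = 21)
  ser <- make_bleach_series(rates, n_timepoints = 60, i0 = 5000,
                            noise_sd = 25, seed = 8)
  st2 <- photobleach_stats(ser, k = 3)
  t_end <- 59; k <- 3
  drop_true <- function(r) {
    s <- mean(exp(-r * (0:2))); e <- mean(exp(-r * (57:59)))
    100 * (1 - e / s)
  }
  expect_equal(st2$median, median(vapply(rates, drop_true, numeric(1))),
               tolerance = 2)
  expect_error(photobleach_stats(matrix(1, 1, 3)), "timepoints")
})

test_that("end-to-end: dual-view acquisition to recovered PSF within 5%", {
  spec <- phantom_spec(size_um = c(12, 12, 12), voxel_um = 0.1, n_beads = 5,
                       fwhm_um = c(0.6, 0.65, 1.3), background = 2,
                       peak_photons = 5000, read_noise_sd = 1, seed = 12,
                       min_separation_um = 3.5)
  ph <- make_bead_phantom(spec)
  acq <- make_oblique_acquisition(ph$volume, opm_angle_deg = 35)
  grid <- gt_grid(ph$volume)
  v1 <- deskew(acq$view1, grid)
  v2 <- deskew(acq$view2, grid)
  tr <- register_views(v1, v2)
  expect_lt(max(abs(tr$translation_vox)), 0.5)
  fused <- fuse(v1, v2, tr)
  recs <- measure_beads(fused, fit_half_um = c(1.2, 1.2, 2.5))
  inc <- recs[recs$included, ]
  expect_gte(nrow(inc), 3)
  expect_equal(median(inc$fwhm_x), 0.6, tolerance = 0.05)
  expect_equal(median(inc$fwhm_y), 0.65, tolerance = 0.05)
  expect_equal(median(inc$fwhm_z), 1.3, tolerance = 0.05)
})
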