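# Geometric aperture model: half angles, solid angles, effective NAs, RCE.

test_that("half_angle matches closed-form arcsin values and rejects na > n", {
  expect_equal(half_angle(1.0, 1.0), 90)
  expect_equal(half_angle(1.2, 1.333), asin(1.2 / 1.333) * 180 / pi)
  expect_equal(half_angle(0.95, 1.0), asin(0.95) * 180 / pi)
  expect_error(half_angle(1.4, 1.333), "cannot exceed")
  expect_error(half_angle(0, 1), "positive")
})

test_that("cone_solid_angle: closed form, bounds, strict monotonicity", {
  expect_equal(cone_solid_angle(90), 2 * pi)
  expect_equal(cone_solid_angle(0), 0)
  expect_equal(cone_solid_angle(64.2), 2 * pi * (1 - cos(64.2 * pi / 180)))
  expect_error(cone_solid_angle(91), "\\[0, 90\\]")
  a <- seq(1, 90, by = 1)
  expect_true(all(diff(cone_solid_angle(a)) > 0))
})

test_that("min_opm_angle reproduces the 26-degree primary-NA limit", {
  expect_equal(round(min_opm_angle(objective_spec(1.2, 1.333))), 26)
  expect_equal(min_opm_angle(objective_spec(1.2, 1.333)),
               90 - asin(1.2 / 1.333) * 180 / pi)
  expect_equal(min_opm_angle(objective_spec(1.0, 1.0)), 0)
  expect_equal(min_opm_angle(objective_spec(1.15, 1.333)),
               90 - asin(1.15 / 1.333) * 180 / pi)
})

test_that("mirror tilt is half the OPM angle; views separate by twice", {
  expect_equal(mirror_normal_tilt(35), 17.5)
  expect_equal(mirror_normal_tilt(45), 22.5)
  expect_equal(mirror_normal_tilt(0), 0)
  expect_equal(view_separation(45), 90)
  expect_equal(view_separation(35), 70)
  expect_equal(view_separation(0), 0)
})

test_that("remote magnification is the index ratio", {
  expect_equal(remote_magnification(1.333, 1.0), 1.333)
  expect_equal(remote_magnification(1.0, 1.0), 1.0)
  expect_equal(remote_magnification(1.52, 1.0), 1.52)
})

test_that("effective NAs: instrument values at 35 deg, limits at 0 and 45", {
  nas <- effective_nas(geom35)
  expect_equal(round(nas$latitudinal_na, 2), 1.2)
  expect_equal(round(nas$longitudinal_na, 2), 1.03)

  nas0 <- effective_nas(geom0)
  expect_equal(nas0$latitudinal_na, 1.2, tolerance = 1e-6)
  expect_equal(nas0$longitudinal_na, 1.2, tolerance = 1e-6)

  # independent in-plane interval-intersection oracle at 45 deg
  a1 <- asin(1.2 / 1.333) * 180 / pi
  a3 <- asin(0.95) * 180 / pi
  half_range <- (min(a1, 45 + a3) - max(-a1, 45 - a3)) / 2
  nas45 <- effective_nas(geom45)
  expect_equal(nas45$longitudinal_na, 1.333 * sin(half_range * pi / 180),
               tolerance = 1e-6)
  # latitudinal never exceeds the primary NA
  for (th in c(0, 20, 35, 45, 60)) {
    g <- suppressWarnings(dopm_geometry(th))
    n <- effective_nas(g)
    expect_lte(n$latitudinal_na, 1.2 + 1e-9)
    expect_lte(n$longitudinal_na, n$latitudinal_na + 1e-9)
  }
})

test_that("intersection solid angle: coaxial and disjoint limits", {
  rep0 <- intersection_solid_angle(geom0, n_points = 1e5)
  expect_equal(rep0$omega_opm, rep0$omega_o1, tolerance = 1e-9)
  expect_equal(rep0$omega_o1,
               cone_solid_angle(half_angle(1.2, 1.333)))

  # disjoint: tiny tertiary cone tilted far away
  g <- suppressWarnings(system_geometry(
    objective_spec(0.3, 1.333), objective_spec(0.1, 1.0), 80))
  expect_warning(repd <- intersection_solid_angle(g, n_points = 1e5),
                 "do not intersect")
  expect_equal(repd$omega_opm, 0)

  expect_error(intersection_solid_angle(geom35, n_points = 100),
               "accuracy floor")
})

test_that("Fibonacci quadrature agrees with a 1e7 Monte-Carlo oracle within 1%", {
  for (th in c(35, 50)) {
    g <- dopm_geometry(th)
    est <- intersection_solid_angle(g, n_points = 1e6)$omega_opm
    mc <- mc_intersection_solid_angle(g, n = 1e7)
    expect_equal(est, mc, tolerance = 0.01)
  }
})

test_that("transmission budget and RCE arithmetic", {
  tb <- transmission_budget(geom35, "static")
  expect_equal(tb$t_optics, 0.9^2 * 0.8)
  expect_equal(tb$t_pbs_fluo, 0.75)
  expect_equal(transmission_budget(geom35, "tumbling")$t_pbs_fluo, 0.50)

  # theta = 0: solid-angle ratio is exactly 1, so RCE reduces to the
  # transmission product
  g0_ideal <- system_geometry(objective_spec(1.2, 1.333),
                              objective_spec(0.95, 1.0, 1.0), 0, t_pbs = 1)
  expect_equal(geometric_rce(g0_ideal, "tumbling", n_points = 1e5), 0.5)
  g0 <- dopm_geometry(0)
  expect_equal(geometric_rce(g0, "static", n_points = 1e5),
               0.75 * 0.81 * 0.8, tolerance = 1e-9)

  # monotone non-increasing in the OPM angle for fixed objectives
  rces <- vapply(c(0, 10, 20, 30, 40, 50),
                 function(th) suppressWarnings(
                   geometric_rce(dopm_geometry(th), "tumbling",
                                 n_points = 2e5)),
                 numeric(1))
  expect_true(all(diff(rces) <= 1e-6))
})

test_that("fibonacci_directions: unit norms, cap coverage, quasi-uniformity", {
  d <- fibonacci_directions(4, 180)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 4), tolerance = 1e-12)

  # <cos theta> over a uniform hemisphere is 1/2
  h <- fibonacci_directions(1000, 90)
  expect_equal(mean(h[, 3]), 0.5, tolerance = 0.01)
  expect_true(all(h[, 3] >= 0))

  # nearest-neighbor angular spacing within 2x of sqrt(2*pi/n) on the
  # hemisphere (checked on a subsample to bound runtime)
  n <- 15000
  hh <- fibonacci_directions(n, 90)
  set.seed(1)
  sub <- sample(n, 200)
  g <- hh %*% t(hh[sub, , drop = FALSE])
  g[cbind(sub, seq_along(sub))] <- -1  # exclude self
  nn_ang <- acos(pmin(1, apply(g, 2, max)))
  expect_lt(max(nn_ang), 2 * sqrt(2 * pi / n))

  expect_error(fibonacci_directions(0), "at least 1")
})

test_that("config round trip through JSON", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    primary = list(na = 1.2, immersion_index = 1.333),
    secondary_tertiary = list(na = 0.95, immersion_index = 1.0,
                              single_pass_transmission = 0.9),
    opm_angle_deg = 35, t_pbs = 0.8, coating = "silver_sio2"),
    path, auto_unbox = TRUE)
  cfg <- read_system_config(path)
  expect_s3_class(cfg$geometry, "system_geometry")
  expect_equal(cfg$geometry$opm_angle_deg, 35)
  expect_equal(cfg$geometry$secondary_tertiary$single_pass_transmission, 0.9)
  expect_equal(cfg$coating$name, "silver_sio2")
  unlink(path)
})
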