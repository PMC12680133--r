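# Vectorial ray trace: ensembles, elements, energy bookkeeping and the
# collection-efficiency figures.

test_that("ray fan: count, O1-cone fraction, overrides", {
  fan <- build_ray_fan(geom35)
  expect_equal(nrow(fan$k), 15000)
  # fraction inside the O1 cone over the hemisphere is (1 - cos a1)
  a1 <- asin(1.2 / 1.333)
  expect_equal(mean(fan$inside_o1), 1 - cos(a1), tolerance = 0.01)
  expect_equal(nrow(build_ray_fan(geom35, n = 100)$k), 100)
})

test_that("dipole ensembles: weights and photoselection", {
  tum <- dipole_ensemble(7500, "tumbling")
  expect_true(all(tum$weights == 1))

  # perpendicular dipole has zero photoselection weight
  sta <- dipole_ensemble(4, "static", excitation = c(1, 0, 0))
  w_perp <- as.numeric(sta$d %*% c(1, 0, 0))^2
  expect_equal(sta$weights, w_perp)

  # <cos^2> over uniform orientations is 1/3
  sta2 <- dipole_ensemble(7500, "static")
  expect_equal(mean(sta2$weights), 1 / 3, tolerance = 0.01)

  expect_error(dipole_ensemble(10, "static", excitation = c(0, 0, 0)),
               "zero-norm")
})

test_that("dipole far field: transverse projection with sin scaling", {
  # perpendicular: field along the dipole, maximal
  E <- dipole_farfield(c(1, 0, 0), c(0, 0, 1))
  expect_equal(E, c(1, 0, 0))
  # parallel: zero field
  expect_equal(dipole_farfield(c(0, 0, 1), c(0, 0, 1)), c(0, 0, 0))
  # 45 degrees: magnitude sin(45) of maximal
  d45 <- c(1, 0, 1) / sqrt(2)
  E45 <- dipole_farfield(d45, c(0, 0, 1))
  expect_equal(sqrt(sum(E45^2)), sin(pi / 4), tolerance = 1e-12)
  # always transverse
  k <- fibonacci_directions(50, 180)
  d <- fibonacci_directions(50, 180)[50:1, ]
  E <- dipole_farfield(d, k)
  expect_lt(max(abs(rowSums(E * k))), 1e-12)
})

test_that("optical elements: mirror, polarizers, waveplate identities", {
  # ideal mirror at normal incidence: k -> -k, |E| preserved
  k <- matrix(c(0, 0, 1), 1)
  m <- mirror_element(k, c(0, 0, 1), coating_presets("perfect"))
  expect_equal(m$k_out, matrix(c(0, 0, -1), 1))
  E <- c(0.6, 0.8i, 0)
  Eout <- drop(m$op[1, , ] %*% E)
  expect_equal(sqrt(sum(Mod(Eout)^2)), 1, tolerance = 1e-12)

  # Householder reflection preserves |k|, |E| and transversality for a
  # perfect mirror at oblique incidence
  kk <- fibonacci_directions(100, 60)
  mm <- mirror_element(kk, c(sin(0.3), 0, cos(0.3)),
                       coating_presets("perfect"))
  expect_equal(sqrt(rowSums(mm$k_out^2)), rep(1, 100), tolerance = 1e-12)
  for (i in c(1, 50, 100)) {
    Ein <- dipole_farfield(c(0.3, 0.5, sqrt(1 - 0.34)), kk[i, ])
    Eo <- drop(mm$op[i, , ] %*% Ein)
    expect_equal(sum(Mod(Eo)^2), sum(Mod(Ein)^2), tolerance = 1e-12)
    expect_lt(abs(sum(Eo * mm$k_out[i, ])), 1e-12)
  }
  expect_error(mirror_element(k, c(0, 0, 2)), "unit vector")

  # crossed ideal polarizers in series: zero field
  px <- jones_polarizer(c(1, 0, 0))
  py <- jones_polarizer(c(0, 1, 0))
  expect_equal(max(Mod(py %*% px)), 0)

  # QWP at 45 deg converts x-linear to circular
  q <- jones_waveplate(90, 45)
  Eq <- drop(q %*% c(1, 0, 0))
  expect_equal(Mod(Eq[1]), Mod(Eq[2]), tolerance = 1e-12)
  ph <- Arg(Eq[2] / Eq[1])
  expect_equal(abs(ph), pi / 2, tolerance = 1e-12)
})

test_that("chain is energy conserving and linear with ideal elements", {
  ch <- precompute_chain(geom0, n_rays = 4000, pbs = FALSE, qwp = FALSE)
  eff <- ensemble_efficiency(geom0, "tumbling", chain = ch,
                             n_dipoles = 2000)
  expect_equal(eff$fraction_vs_o1, 1, tolerance = 0.005)

  # linearity of the per-ray operator
  A <- ch$A[17, , ]
  a <- c(1, 2i, 0); b <- c(0, 1, -1)
  expect_equal(A %*% (a + b), A %*% a + A %*% b, tolerance = 1e-12)
})

test_that("PBS/QWP double pass at 0 deg is exactly 0.5 per ray (unpolarized)", {
  ch <- precompute_chain(geom0, n_rays = 3000)
  en <- dopmtools:::chain_energies(ch, diag(3) / 3)
  frac <- en$out[ch$passes] / en$collected[ch$passes]
  expect_equal(frac, rep(0.5, sum(ch$passes)), tolerance = 1e-12)
})

test_that("collection figures: 50% tumbling, 71% static, 75% low-NA limit", {
  ch <- precompute_chain(geom0, n_rays = 15000)
  tum <- ensemble_efficiency(geom0, "tumbling", chain = ch)$fraction_vs_o1
  sta <- ensemble_efficiency(geom0, "static", chain = ch)$fraction_vs_o1
  expect_equal(tum, 0.50, tolerance = 1e-3)
  expect_equal(sta, 0.71, tolerance = 0.01)

  # analytic low-NA anisotropy limits
  expect_equal(pbs_lowna_transmission(0.4), 0.75)
  expect_equal(pbs_lowna_transmission(0), 0.5)

  # static-regime efficiency converges monotonically to 0.75 as NA -> 0
  effs <- vapply(c(0.6, 0.3, 0.1, 0.05), function(na) {
    g <- system_geometry(objective_spec(na, 1.333),
                         objective_spec(0.95, 1.0, 0.9), 0, 0.8)
    ensemble_efficiency(g, "static", n_rays = 8000,
                        n_dipoles = 4000)$fraction_vs_o1
  }, numeric(1))
  expect_true(all(diff(effs) > 0))
  expect_equal(effs[4], 0.75, tolerance = 0.002)
})

test_that("results are stable under doubled sampling (0.2%)", {
  base <- ensemble_efficiency(geom35, "static",
                              mirror = coating_presets("silver_sio2"),
                              n_rays = 15000, n_dipoles = 7500)
  dbl <- ensemble_efficiency(geom35, "static",
                             mirror = coating_presets("silver_sio2"),
                             n_rays = 30000, n_dipoles = 15000)
  expect_equal(base$fraction_vs_o1, dbl$fraction_vs_o1, tolerance = 0.002)
})

test_that("empty ensemble and unknown regime are rejected", {
  expect_error(ensemble_efficiency(geom0, "tumbling", n_rays = 1000,
                                   n_dipoles = 0),
               "empty")
  expect_error(ensemble_efficiency(geom0, "spinning", n_rays = 1000))
})

test_that("pupil map: symmetry, bookkeeping, tilt asymmetry", {
  pm0 <- pupil_map(geom0, "tumbling", n_rays = 10000, n_dipoles = 2000,
                   n_bins = 16)
  # 180-degree rotational symmetry at 0 deg: opposite half-pupil energies
  # agree within sampling tolerance along both axes
  img <- pm0$intensity
  tot <- sum(img)
  expect_equal(sum(img[1:8, ]) / tot, sum(img[9:16, ]) / tot,
               tolerance = 0.02)
  expect_equal(sum(img[, 1:8]) / tot, sum(img[, 9:16]) / tot,
               tolerance = 0.02)

  # energy bookkeeping: integral of the map equals efficiency x O1 energy
  eff <- ensemble_efficiency(geom0, "tumbling", n_rays = 10000,
                             n_dipoles = 2000)
  expect_equal(sum(pm0$intensity),
               eff$fraction_vs_o1 * pm0$o1_energy, tolerance = 1e-6)

  # the tilted tertiary cone clips one side of the pupil at 35 deg
  pm35 <- pupil_map(geom35, "tumbling", n_rays = 10000, n_dipoles = 2000,
                    n_bins = 16)
  col_en0 <- rowSums(pm0$intensity) / sum(pm0$intensity)
  col_en35 <- rowSums(pm35$intensity) / sum(pm35$intensity)
  # clipped side (positive-x half, which reflects away from the tilted
  # acceptance cone) loses relative energy compared with the coaxial case
  half <- seq_len(8)
  expect_lt(sum(col_en35[half + 8]), sum(col_en0[half + 8]))

  expect_error(pupil_map(geom0, "tumbling", n_bins = 4), "at least 8")
})
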