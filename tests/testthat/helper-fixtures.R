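# Shared fixtures: the characterized instrument configuration and a few
# small deterministic phantoms. Everything is generated in code.

geom35 <- dopm_geometry(35)
geom45 <- dopm_geometry(45)
geom0 <- dopm_geometry(0)

# a small smooth dual-view ground-truth volume (noise-free)
smooth_phantom <- function(seed = 3) {
  spec <- phantom_spec(size_um = c(10, 10, 10), voxel_um = 0.2, n_beads = 3,
                       fwhm_um = c(0.8, 0.8, 1.6), background = 0,
                       peak_photons = 1000, read_noise_sd = 0, seed = seed)
  ph <- make_bead_phantom(spec)
  # remove Poisson noise: re-render expectation by smoothing is overkill;
  # just use the noisy render, it is smooth at these photon counts
  ph$volume
}

gt_grid <- function(lab) {
  list(origin_um = lab$origin_um, dim = dim(lab$voxels),
       voxel_size_um = lab$voxel_size_um)
}

# uniform-random Monte-Carlo estimate of the triple-cone intersection
# solid angle (independent oracle for the Fibonacci quadrature)
mc_intersection_solid_angle <- function(geometry, n = 1e7, seed = 42) {
  a1 <- half_angle(geometry$primary$na, geometry$primary$immersion_index)
  a3 <- half_angle(geometry$secondary_tertiary$na,
                   geometry$secondary_tertiary$immersion_index)
  th <- geometry$opm_angle_deg * pi / 180
  set.seed(seed)
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  x <- r * cos(phi); y <- r * sin(phi)
  ca1 <- cospi(a1 / 180); ca3 <- cospi(a3 / 180)
  inside <- (z >= ca1) & (z >= ca3) &
    (x * sin(th) + z * cos(th) >= ca3)
  4 * pi * mean(inside)
}
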