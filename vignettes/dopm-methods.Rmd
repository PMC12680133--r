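---
title: "Models and methods for dual-view OPM characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dual-view OPM characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopmtools)
```

This vignette documents the models behind `dopmtools`, the assumptions
they rest on, the parameters that matter and their defaults, the numerical
choices, and what the synthetic-data tests do and do not establish.

## The system being modelled

Dual-view oblique plane microscopy (dOPM) images an oblique light sheet
through a single primary objective O1 (here 60×/1.2 NA water immersion),
relays the sample into a remote space under the Botcherby condition
(magnification `n_sample / n_remote` = 1.333, which preserves ray angles),
and re-images the tilted plane with one air objective double-passed as
secondary and tertiary lens (O2/O3, 0.95 NA). A tilted prism mirror with
its normal at half the OPM angle folds the remote arm; translating it
scans the sheet and switches between the two views. Fluorescence transmits
the polarizing beam splitter (PBS), double-passes a quarter-wave plate
(QWP) around the mirror reflection, and returns to the PBS reflection port
toward the camera.

## Aperture geometry

Because angles are preserved between sample and remote space, the three
collection cones can be compared in one angular space: the primary cone
(half angle `asin(1.2/1.333)` = 64.2°) about the optical axis, the
secondary cone (`asin(0.95)` = 71.8°) coaxial, and the tertiary cone
(71.8°) about an axis tilted by the OPM angle θ.

* `effective_nas()` reports the **longitudinal NA** as
  `n · sin` of half the in-tilt-plane angular intersection
  `[-64.2°, 64.2°] ∩ [θ − 71.8°, θ + 71.8°]`, and the **latitudinal NA**
  from the maximal out-of-plane half-extent of the intersection (found on
  a 2001-point in-plane grid; the extremum is smooth, so grid error is
  negligible at display precision). At θ = 35° this gives (1.20, 1.03).
* `intersection_solid_angle()` integrates the triple-cone intersection
  with a deterministic Fibonacci lattice on the primary cap (default 10⁶
  points, refusing fewer than 10⁴). Quadrature error is O(1/√N) on the
  boundary band only; at the default it is well below the 1 % tolerance
  asserted against a 10⁷-sample Monte-Carlo oracle.
* `geometric_rce()` multiplies the solid-angle ratio by
  `T_optics = T_o23² · T_pbs` (0.9² × 0.8 = 0.648 measured) and by the
  ideal PBS double-pass fluorescence factor `T_pbs_fluo`, 0.50 for
  rapidly tumbling fluorophores and 0.75 for static photoselected ones.
  These are the low-NA anisotropy limits `(1 + 2r)/(2 + r)` at r = 0 and
  r = 0.4 (`pbs_lowna_transmission()`).

Configurations whose cones fail to intersect return zeros with a warning
rather than an error, so angle sweeps stay plottable.

## Vectorial ray trace

Each ray carries a unit wavevector and a transverse complex field
3-vector. Elements act as per-ray 3×3 operators:

* **Objectives** rotate the field in the meridional plane (Rodrigues
  rotation taking the ray onto the lens axis, or its inverse).
* **PBS ports and the QWP** act on lab transverse coordinates
  (projectors onto x̂/ŷ; QWP retardance 90° at a 45° fast axis).
* **The tilted mirror** Householder-reflects the wavevector
  (`k − 2(k·n̂)n̂`) and applies the coating's complex `r_s`, `r_p` in the
  per-ray plane of incidence.

The trace uses a 15,000-direction Fibonacci fan over the hemisphere
(overfilling O1) and a 7,500-orientation Fibonacci dipole ensemble,
uniform-weighted (tumbling) or cos²-weighted by the angle to the
excitation polarization (static photoselection; the excitation axis is
the in-sheet lab x, which coincides with the PBS transmission axis).
Because output energies are quadratic in the dipole moment, the
incoherent ensemble sum per ray reduces exactly to `tr(AᴴA M)` with `M`
the weighted dipole second-moment matrix — the full 15,000 × 7,500
simulation costs O(n_rays) and runs in about a second, with no sampling
error beyond the two Fibonacci lattices themselves.

**Energy bookkeeping and apodization.** Rays represent equal elements of
solid angle, so an ideal aplanatic lens conserves energy per ray and the
√cos θ apodization familiar from Richards–Wolf theory cancels out of all
energy ratios; it would only matter for pupil-plane intensity *densities*.
We therefore apply no apodization factor in the efficiency computation.
This choice is validated rather than assumed: the ideal chain without
PBS/QWP returns fraction 1.000 (energy conservation), the PBS/QWP double
pass at θ = 0 is *exactly* 0.5 per ray for unpolarized light (an
algebraic identity of QWP–mirror–QWP around any real-orthogonal
intermediate), the static ensemble gives 71.0 % at NA 1.2 against the
instrument's quoted 71 %, and the low-NA limit converges to the analytic
75 %.

**Thin films.** `coating_reflectivity()` uses the characteristic-matrix
method with tilted admittances (`n cos θ` for s, `n/cos θ` for p) and
complex propagation cosines on the decaying branch. Conventions: indices
are `n + ik`; the layer phase sign is paired with that choice so
absorbing layers decay; the p basis after reflection is chosen so that
`r_p = r_s` at normal incidence (bare glass gives −0.2 for both) and a
perfect mirror at normal incidence maps E → −E. The implementation is
tested to 10⁻⁶ against an independent multiple-beam (Airy summation)
oracle. Default stacks — perfect, bare silver (0.13 + 3.19i at 520 nm),
silver + 100 nm SiO₂ (1.46), aluminium (0.83 + 6.28i) + 100 nm SiO
(1.95) — are representative, because manufacturers do not disclose exact
protected-mirror recipes; every index and thickness is configurable. The
default wavelength is 520 nm, mid-band of green fluorescent-protein
emission; waveplates are treated as achromatic and dispersionless.

At 35° with the protected-silver stack and measured transmissions the
trace yields ≈ 0.35 (static) and ≈ 0.24 (tumbling) relative collection,
upper bounds consistent with bead measurements of 0.23 and 0.19 that sit
slightly below simulation. Out of scope: coherent (Debye–Wolf) PSF
computation, finite mirror apertures, field-dependent vignetting and
aberrations.

## Light dose

`dose_comparison()` compares total light dose to a centered point object
under equal in-focus detected signal. The widefield stack deposits 1 a.u.
per plane × `n_planes` (default 151). Each of the two sheet views scans a
Gaussian sheet (FWHM 3.0 µm — the worst-case thin-sheet measurement) in
`plane_spacing_um` steps; the sheet peak is set by
`n_views · peak · RC = 1`, i.e. the combined two-view in-focus signal at
relative collection RC equals the widefield frame signal. The ratio
reduces to `n_planes · RC · Δz / (1.0645 · fwhm)` in the continuum limit.

The 1.0 µm plane spacing is *inferred*: it is the spacing under which the
quoted ratios 10.9 (RC 0.23) and 9.0 (RC 0.19) are both exact under this
model, and it is configurable. Note the discrete scan sum only matches
the continuum formula to <1 % once the sheet FWHM exceeds ~1.5 plane
spacings (Poisson-summation error is ~6 % at equality); the defaults are
far inside the valid regime. Photochemistry and nonlinear bleaching
kinetics are out of scope — the model counts photons, nothing more.

## Volume processing

Lab-frame convention: z is distance from the coverslip, the sheet scans
along y, x is the camera column axis; views tilt symmetrically (±θ). A
raw voxel (scan i, row r, column c) sits at
`x = c·p_c`, `y = y₀ + i·Δs + s·r·p_r·cos θ`, `z = r·p_r·sin θ` with
`s = ±1` per view; `y₀` records where the scan started (the positively
sheared view must begin ahead of the volume). `deskew()` inverts this
linear map and resamples by trilinear interpolation onto an axis-aligned
grid (default isotropic at `min(p_r sin θ, p_c)`); `forward_skew()` is
the matching forward model used by the synthetic generators. Round trips
correlate >0.99 with ground truth at 35° and 45°.

`register_views()` estimates only the residual translation (rotation is
fixed by the known geometry) by 3D phase correlation, refined to
sub-voxel precision by the local centroid of the correlation peak, with a
low-confidence flag on weak peaks. `fuse()` is a weighted mean (default
½, ½); the instrument study saw no resolution gain from fusion alone, and
multiview deconvolution is deliberately out of scope. Full rigid
refinement beyond translation is not implemented; phase correlation is a
documented stand-in for the instrument's (unpublished) registration step.

## Metrology

* `detect_beads()`: 26-neighborhood maxima above `background +
  8·MAD`, border-excluded, with *both* members of any pair closer than
  3 µm excluded as crowded. The SNR default is deliberately high because
  million-voxel Poisson backgrounds produce >5 SD maxima by chance alone.
* `measure_fwhm()`: 1D Gaussian fits (`stats::nls`, moment starts)
  through the sub-voxel centroid; FWHM = 2.3548 σ; inclusion requires
  r² ≥ 0.9 per axis. The estimator is unbiased within 2 % for Gaussian
  beads sampled at ≥4 voxels per FWHM at SNR ≥ 10.
* `bead_sectioning()`: axial profile of the laterally integrated signal,
  FWHM by interpolated half-maximum crossings. With a finite integration
  window, defocused energy escapes laterally, so this reads wider than
  the bead axial FWHM for realistic PSFs — mirroring the instrument
  observation that sheet-based sectioning reads wider still.
* `summarize_records()`: median, IQR and a distribution-free 95 % CI on
  the median from binomial order statistics — deterministic, unlike a
  bootstrap, which matters for reproducible tests. Percent changes
  between configurations use printed-precision medians.
* `relative_efficiency()`: square signal ROI sized from the analytic
  Airy encircled energy `EE(v) = 1 − J₀²(v) − J₁²(v)` at 99 % (≈4.4 µm at
  NA 1.2, 520 nm — the Airy EE converges slowly, ~2/(πv)), adjacent
  equal-size background ROI, then `η = (S_d − B_d)/(S_e − B_e)`.
* `photobleach_stats()`: per-ROI percent drop using means of the first
  and last k = 3 frames (the instrument's exact start/end windows are not
  published), summarized as median ± IQR.

## Synthetic data: what a green test establishes

The generators emulate the instrument's calibration samples: isolated
sub-resolution beads rendered as (optionally tilted) anisotropic
Gaussians with Poisson + Gaussian read noise over a constant background
(default FWHM targets 0.29/0.31/0.83 µm — the fused 35° medians), a
Gaussian-profile thin sheet, dual-view sheared acquisitions via the exact
forward model, and exponential bleaching series. All randomness is seeded
and local (the caller's RNG state is untouched).

They do **not** emulate scattering, refractive-index heterogeneity,
aberrated or diffraction-structured PSFs, camera fixed-pattern noise, or
registration rotations. A green end-to-end test therefore establishes
that the *pipeline* — forward model, deskew, registration, fusion,
detection, fitting, summary — is self-consistent to its stated
tolerances (PSF recovery within 5 %, shifts within 0.5 voxel), not that
the instrument achieves any particular resolution. The printed absolute
medians of the real system are measurement results and are intentionally
not asserted anywhere.

## Known limitations

* No TIFF/OME-TIFF I/O in this build (no TIFF library in the supported
  dependency set); volumes live in memory and configs/reports are JSON.
* The vectorial model treats tube/relay lenses and filters as
  polarization-neutral and the QWP as ideal at all wavelengths.
* Registration is translation-only; rotations must come from geometry.
* `sheet_sectioning()` fits every lateral column (or a strided subset);
  for very large volumes use the `stride` argument.
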