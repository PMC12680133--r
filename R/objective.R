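#' Objective lens specification
#'
#' Bundle the parameters of a microscope objective that the collection
#' models need: numerical aperture, refractive index of the design
#' immersion medium and the manufacturer single-pass transmission.
#'
#' @param na Numerical aperture (dimensionless), `0 < na <= immersion_index`.
#' @param immersion_index Refractive index of the immersion medium the
#'   objective is designed for (1.0 air, 1.333 water, ...).
#' @param single_pass_transmission Fraction of light transmitted in a single
#'   pass through the objective, in `[0, 1]`.
#'
#' @return An object of class `objective_spec`.
#' @examples
#' primary <- objective_spec(na = 1.2, immersion_index = 1.333)
#' remote  <- objective_spec(na = 0.95, immersion_index = 1.0,
#'                           single_pass_transmission = 0.9)
#' @export
objective_spec <- function(na, immersion_index = 1.0,
                           single_pass_transmission = 1.0) {
  stopifnot(is.numeric(na), length(na) == 1L, is.finite(na),
            is.numeric(immersion_index), length(immersion_index) == 1L,
            is.numeric(single_pass_transmission),
            length(single_pass_transmission) == 1L)
  if (na <= 0) stop("`na` must be positive")
  if (na > immersion_index)
    stop("`na` cannot exceed the immersion refractive index (na = ",
         na, ", n = ", immersion_index, ")")
  if (single_pass_transmission < 0 || single_pass_transmission > 1)
    stop("`single_pass_transmission` must lie in [0, 1]")
  structure(
    list(na = na, immersion_index = immersion_index,
         single_pass_transmission = single_pass_transmission),
    class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("<objective_spec> NA %.3g / n %.4g (T single pass %.3g)\n",
              x$na, x$immersion_index, x$single_pass_transmission))
  invisible(x)
}

#' dOPM system geometry
#'
#' Describe a dual-view oblique plane microscope at the level needed by the
#' collection-efficiency models: the primary objective, the shared
#' secondary/tertiary objective of the remote (folded) arm, the OPM angle of
#' the light sheet with respect to the coverslip, and the measured
#' double-pass transmission of the polarizing beam splitter for on-axis
#' linearly polarized light.
#'
#' The OPM angle must be below 90 degrees. Physically usable light-sheet
#' angles also satisfy `opm_angle_deg >= min_opm_angle(primary)`; smaller
#' angles (including 0) are accepted with a warning because they are needed
#' for collection-efficiency simulations of the folded path alone.
#'
#' @param primary [objective_spec()] of the primary objective (sample side).
#' @param secondary_tertiary [objective_spec()] of the shared remote
#'   objective used as both secondary and tertiary lens.
#' @param opm_angle_deg Light-sheet angle to the coverslip, degrees.
#' @param t_pbs Measured double-pass transmission of the polarizing beam
#'   splitter (plus quarter-wave plate and normal-incidence mirror) for
#'   on-axis linearly polarized light, in `[0, 1]`.
#'
#' @return An object of class `system_geometry`.
#' @examples
#' geom <- dopm_geometry(opm_angle_deg = 35)
#' geom
#' @export
system_geometry <- function(primary, secondary_tertiary, opm_angle_deg,
                            t_pbs = 1.0) {
  stopifnot(inherits(primary, "objective_spec"),
            inherits(secondary_tertiary, "objective_spec"),
            is.numeric(opm_angle_deg), length(opm_angle_deg) == 1L)
  if (opm_angle_deg < 0 || opm_angle_deg >= 90)
    stop("`opm_angle_deg` must lie in [0, 90)")
  if (t_pbs < 0 || t_pbs > 1) stop("`t_pbs` must lie in [0, 1]")
  min_angle <- min_opm_angle(primary)
  if (opm_angle_deg > 0 && opm_angle_deg < min_angle)
    warning(sprintf(
      "OPM angle %.3g deg is below the minimum %.3g deg set by the primary NA; ",
      opm_angle_deg, min_angle),
      "no aperture remains for light-sheet illumination", call. = FALSE)
  structure(
    list(primary = primary, secondary_tertiary = secondary_tertiary,
         opm_angle_deg = opm_angle_deg, t_pbs = t_pbs),
    class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf(
    "<system_geometry> OPM angle %.4g deg, T_PBS %.3g\n", x$opm_angle_deg,
    x$t_pbs))
  cat("  primary:            "); print(x$primary)
  cat("  secondary/tertiary: "); print(x$secondary_tertiary)
  invisible(x)
}

#' Default dOPM system geometry
#'
#' Convenience constructor for the characterized instrument configuration: a
#' 60x/1.2 NA water-immersion primary, a 50x/0.95 air objective double-passed
#' as secondary/tertiary with single-pass transmission 0.9, and a measured
#' PBS double-pass transmission of 0.8.
#'
#' @param opm_angle_deg Light-sheet angle to the coverslip, degrees
#'   (the instrument uses 35 or 45).
#' @param t_pbs Measured PBS double-pass transmission.
#' @return A [system_geometry()] object.
#' @export
dopm_geometry <- function(opm_angle_deg = 35, t_pbs = 0.8) {
  system_geometry(
    primary = objective_spec(1.2, 1.333, 1.0),
    secondary_tertiary = objective_spec(0.95, 1.0, 0.9),
    opm_angle_deg = opm_angle_deg,
    t_pbs = t_pbs)
}
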