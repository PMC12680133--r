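#' Read a system configuration from JSON
#'
#' Load a dOPM system description from a JSON file with fields
#' `primary` and `secondary_tertiary` (each with `na`, `immersion_index`,
#' `single_pass_transmission`), `opm_angle_deg`, `t_pbs` and optionally
#' `coating` (a [coating_presets()] name).
#'
#' @param path Path to the JSON file.
#' @return List with `geometry` (a [system_geometry()]) and `coating`
#'   (a [coating_stack()], perfect mirror if unspecified).
#' @export
read_system_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("primary", "secondary_tertiary", "opm_angle_deg")
  if (!all(need %in% names(cfg)))
    stop("config must contain: ", paste(need, collapse = ", "))
  obj <- function(o) objective_spec(
    na = o$na,
    immersion_index = if (is.null(o$immersion_index)) 1.0 else
      o$immersion_index,
    single_pass_transmission = if (is.null(o$single_pass_transmission)) 1.0
      else o$single_pass_transmission)
  geom <- system_geometry(
    obj(cfg$primary), obj(cfg$secondary_tertiary),
    cfg$opm_angle_deg,
    t_pbs = if (is.null(cfg$t_pbs)) 1.0 else cfg$t_pbs)
  coating <- if (is.null(cfg$coating)) coating_presets("perfect")
    else coating_presets(cfg$coating)
  list(geometry = geom, coating = coating)
}

#' Write an analysis report to JSON
#'
#' Serializes a named list of scalars/vectors (an aperture report,
#' efficiency report, dose result, bead summary, ...) to pretty-printed
#' JSON with full numeric precision.
#'
#' @param x A (possibly classed) list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
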