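#' Layered mirror coating stack
#'
#' Describe a mirror as a (possibly absorbing) substrate plus an ordered
#' list of thin-film layers, for computing the complex reflection
#' coefficients needed by the vectorial ray trace.
#'
#' @param substrate_index Complex refractive index of the substrate
#'   (e.g. `0.13 + 3.19i` for silver at 520 nm).
#' @param layers List of layers ordered from the substrate outward, each a
#'   list with `index` (complex refractive index) and `thickness_nm`
#'   (physical thickness, nm, `>= 0`).
#' @param name Label for the stack. The special name `"perfect"` denotes an
#'   ideal lossless mirror with `|r| = 1` for both polarizations and no
#'   layers.
#' @return An object of class `coating_stack`.
#' @seealso [coating_presets()], [coating_reflectivity()]
#' @export
coating_stack <- function(substrate_index, layers = list(), name = "custom") {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "perfect" && length(layers) > 0L)
    stop("a \"perfect\" stack must have no layers")
  for (ly in layers) {
    if (!all(c("index", "thickness_nm") %in% names(ly)))
      stop("each layer needs `index` and `thickness_nm`")
    if (ly$thickness_nm < 0) stop("layer thicknesses must be >= 0")
  }
  structure(
    list(substrate_index = as.complex(substrate_index),
         layers = layers, name = name),
    class = "coating_stack")
}

#' @export
print.coating_stack <- function(x, ...) {
  cat(sprintf("<coating_stack> \"%s\": substrate n = %s, %d layer(s)\n",
              x$name, format(x$substrate_index), length(x$layers)))
  for (ly in x$layers)
    cat(sprintf("  layer n = %s, d = %.4g nm\n", format(as.complex(ly$index)),
                ly$thickness_nm))
  invisible(x)
}

#' Preset mirror coatings
#'
#' Default coating stacks used by the collection-efficiency simulations at
#' the default wavelength of 520 nm:
#' * `"perfect"` — ideal mirror, `|r| = 1` for s and p;
#' * `"bare_silver"` — uncoated silver, n = 0.13 + 3.19i;
#' * `"silver_sio2"` — silver protected by 100 nm of silica (n = 1.46);
#' * `"aluminum_sio"` — aluminium (n = 0.83 + 6.28i) protected by 100 nm of
#'   silicon monoxide (n = 1.95).
#'
#' Exact commercial protected-mirror coating specifications are proprietary;
#' thicknesses and indices here are representative and configurable through
#' [coating_stack()].
#'
#' @param name One of `"perfect"`, `"bare_silver"`, `"silver_sio2"`,
#'   `"aluminum_sio"`.
#' @return A [coating_stack()].
#' @export
coating_presets <- function(name = c("perfect", "bare_silver", "silver_sio2",
                                     "aluminum_sio")) {
  name <- match.arg(name)
  n_ag <- 0.13 + 3.19i
  n_al <- 0.83 + 6.28i
  switch(name,
    perfect = coating_stack(NA_complex_, list(), "perfect"),
    bare_silver = coating_stack(n_ag, list(), "bare_silver"),
    silver_sio2 = coating_stack(
      n_ag, list(list(index = 1.46 + 0i, thickness_nm = 100)), "silver_sio2"),
    aluminum_sio = coating_stack(
      n_al, list(list(index = 1.95 + 0i, thickness_nm = 100)), "aluminum_sio"))
}

#' Complex reflectivity of a coated mirror
#'
#' Complex reflection coefficient of a layered coating stack by the
#' characteristic (transfer) matrix method with tilted optical admittances:
#' for each layer the phase thickness is
#' `delta = 2 pi n d cos(t) / lambda` and the admittance is `n cos(t)` for
#' s polarization or `n / cos(t)` for p, where `cos(t)` is the (complex)
#' propagation cosine from Snell's law. The sign convention makes
#' `r_s = r_p = (n1 - n2) / (n1 + n2)` at normal incidence.
#'
#' The incident medium must be non-absorbing. A `"perfect"` stack returns
#' -1 for both polarizations at every incidence angle.
#'
#' @param stack A [coating_stack()].
#' @param incidence_deg Angle of incidence, degrees, in `[0, 90)`. May be a
#'   vector.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param polarization `"s"` (perpendicular to the plane of incidence) or
#'   `"p"` (parallel).
#' @param incident_index Real refractive index of the incident medium
#'   (default 1, air/remote space).
#' @return Complex reflection coefficient(s), same length as
#'   `incidence_deg`.
#' @examples
#' # Fresnel reflection from bare glass at normal incidence: -0.2
#' glass <- coating_stack(1.5 + 0i)
#' coating_reflectivity(glass, 0, 520, "s")
#' @export
coating_reflectivity <- function(stack, incidence_deg, wavelength_nm = 520,
                                 polarization = c("s", "p"),
                                 incident_index = 1.0) {
  stopifnot(inherits(stack, "coating_stack"), is.numeric(incidence_deg))
  polarization <- match.arg(polarization)
  if (any(incidence_deg < 0 | incidence_deg >= 90))
    stop("`incidence_deg` must lie in [0, 90)")
  if (is.complex(incident_index) && Im(incident_index) != 0)
    stop("absorbing incident media are not supported")
  if (stack$name == "perfect")
    return(rep(-1 + 0i, length(incidence_deg)))

  n0 <- as.numeric(incident_index)
  sin0 <- sinpi(incidence_deg / 180)
  cos0 <- cospi(incidence_deg / 180)

  # complex propagation cosine with the decaying branch (Im(n cos) >= 0)
  prop_cos <- function(n) {
    ct <- sqrt(1 - (n0 * sin0 / n)^2)
    flip <- Im(n * ct) < 0
    ct[flip] <- -ct[flip]
    ct
  }
  admittance <- function(n, ct) {
    if (polarization == "s") n * ct else n / ct
  }

  eta0 <- admittance(as.complex(n0), as.complex(cos0))
  cs <- prop_cos(stack$substrate_index)
  eta_sub <- admittance(stack$substrate_index, cs)

  # characteristic matrix product, traversed from the incident side inward
  b <- rep(1 + 0i, length(incidence_deg))
  c_ <- eta_sub
  for (ly in rev(stack$layers)) {
    n <- as.complex(ly$index)
    ct <- prop_cos(n)
    eta <- admittance(n, ct)
    # phase sign paired with the n + ik index convention (fields go as
    # exp(+i k z - i w t)), so absorbing layers decay
    delta <- -2 * pi * n * ly$thickness_nm * ct / wavelength_nm
    cd <- cos(delta); sd <- sin(delta)
    b_new <- cd * b + 1i * sd / eta * c_
    c_new <- 1i * eta * sd * b + cd * c_
    b <- b_new; c_ <- c_new
  }
  (eta0 * b - c_) / (eta0 * b + c_)
}
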