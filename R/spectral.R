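# Spectral containers, visual-pigment templates and photon-flux bookkeeping.
#
# All spectra live on a shared uniform wavelength grid (default 300-780 nm in
# 1 nm steps, the usual spectroradiometer convention). Power densities are in
# photons cm^-2 s^-1 nm^-1; sensitivities and transmissions are dimensionless
# in [0, 1].

#' Default wavelength grid
#'
#' @param from,to,by grid limits and spacing in nm.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_grid <- function(from = 300, to = 780, by = 1) seq(from, to, by = by)

#' Sampled spectral function
#'
#' A function of wavelength sampled on a strictly increasing, uniform grid.
#' Three kinds are distinguished: `power_density` (photons cm^-2 s^-1 nm^-1,
#' non-negative), `sensitivity` and `transmission` (both dimensionless in
#' \[0, 1\]).
#'
#' @param wavelengths numeric, nm, strictly increasing with constant spacing.
#' @param values numeric, same length as `wavelengths`.
#' @param kind one of `"power_density"`, `"sensitivity"`, `"transmission"`.
#' @return An object of class `spectral_function` with fields `wavelength`,
#'   `value` and `kind`.
#' @export
spectral_function <- function(wavelengths, values,
                              kind = c("power_density", "sensitivity", "transmission")) {
  kind <- match.arg(kind)
  if (!is.numeric(wavelengths) || !is.numeric(values) ||
      length(wavelengths) != length(values) || length(wavelengths) < 2L)
    stop("wavelengths and values must be numeric vectors of equal length >= 2")
  dw <- diff(wavelengths)
  if (any(dw <= 0)) stop("wavelengths must be strictly increasing")
  if (max(abs(dw - dw[1])) > 1e-9 * dw[1]) stop("wavelength grid must be uniform")
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectral values must be finite and non-negative")
  if (kind != "power_density" && any(values > 1 + 1e-12))
    stop(kind, " values must lie in [0, 1]")
  structure(list(wavelength = as.numeric(wavelengths),
                 value = as.numeric(values),
                 kind = kind),
            class = "spectral_function")
}

#' @export
print.spectral_function <- function(x, ...) {
  cat(sprintf("<spectral_function: %s, %d samples, %g-%g nm (step %g nm)>\n",
              x$kind, length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$wavelength[2] - x$wavelength[1]))
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b) {
  if (length(a$wavelength) != length(b$wavelength) ||
      max(abs(a$wavelength - b$wavelength)) > 1e-9)
    stop("spectral functions are not on a shared wavelength grid")
  invisible(NULL)
}

#' Visual pigment absorbance template (A1 nomogram)
#'
#' Evaluates the Govardovskii A1 visual-pigment template (alpha plus beta
#' band) for a pigment with peak sensitivity `lambda_max`, normalised so the
#' grid point nearest `lambda_max` has the value 1.
#'
#' The alpha band is
#' \deqn{S_\alpha(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with `x = lambda_max / lambda`, constants `A = 69.7`, `B = 28`,
#' `C = -14.9`, `D = 0.674`, `b = 0.922`, `c = 1.104` and
#' `a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940)`. The beta band is
#' a Gaussian of amplitude 0.26 centred at `189 + 0.315 lambda_max` with width
#' parameter `-40.5 + 0.195 lambda_max`.
#'
#' @param lambda_max peak wavelength in nm; must lie within the grid span.
#' @param grid wavelength grid in nm (must cover at least 350-700 nm).
#' @return A `spectral_function` of kind `"sensitivity"` with peak value 1.
#' @export
pigment_nomogram <- function(lambda_max, grid = default_grid()) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L)
    stop("lambda_max must be a single number")
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("lambda_max (", lambda_max, " nm) lies outside the wavelength grid")
  if (min(grid) > 350 || max(grid) < 700)
    stop("grid must cover at least 350-700 nm")
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lam_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lam_beta) / b_beta)^2)
  s <- alpha + beta
  s <- s / max(s)
  out <- spectral_function(grid, s, "sensitivity")
  attr(out, "lambda_max") <- lambda_max
  out
}

#' Photopigment description
#'
#' @param name `"rod"` or `"melanopsin"`.
#' @param lambda_max peak wavelength, nm. Defaults: rod 498 nm, melanopsin
#'   480 nm (standard mouse values).
#' @param in_vivo logical; apply pre-receptoral (lens) filtering when building
#'   the in vivo sensitivity.
#' @return An object of class `photopigment`.
#' @export
photopigment <- function(name = c("rod", "melanopsin"), lambda_max = NULL,
                         in_vivo = TRUE) {
  name <- match.arg(name)
  if (is.null(lambda_max))
    lambda_max <- c(rod = 498, melanopsin = 480)[[name]]
  structure(list(name = name, lambda_max = lambda_max, in_vivo = in_vivo),
            class = "photopigment")
}

#' Built-in lens transmission template
#'
#' Sigmoidal short-wavelength cut standing in for ocular pre-receptoral
#' filtering: `T(lambda) = 1 / (1 + exp(-(lambda - lambda_half) / scale))`.
#' This is a synthetic template (half-transmission 360 nm, scale 30 nm by
#' default), user-replaceable by a measured curve loaded with [read_spd()].
#'
#' @param grid wavelength grid, nm.
#' @param lambda_half wavelength of half transmission, nm.
#' @param scale steepness scale, nm.
#' @return A `spectral_function` of kind `"transmission"`.
#' @export
lens_transmission <- function(grid = default_grid(), lambda_half = 360, scale = 30) {
  spectral_function(grid, 1 / (1 + exp(-(grid - lambda_half) / scale)),
                    "transmission")
}

#' Apply pre-receptoral filtering to a sensitivity
#'
#' Pointwise product of a pigment sensitivity with an ocular-media
#' transmission curve, renormalised to peak 1 (in vivo spectral sensitivity).
#'
#' @param sensitivity a `spectral_function` of kind `"sensitivity"`.
#' @param lens a `spectral_function` of kind `"transmission"` on the same grid.
#' @return Filtered, renormalised `spectral_function` (sensitivity).
#' @export
apply_prereceptoral_filter <- function(sensitivity, lens) {
  stopifnot(inherits(sensitivity, "spectral_function"),
            inherits(lens, "spectral_function"))
  if (sensitivity$kind != "sensitivity" || lens$kind != "transmission")
    stop("expected a sensitivity and a transmission spectral function")
  stop_if_grid_mismatch(sensitivity, lens)
  v <- sensitivity$value * lens$value
  if (max(v) <= 0) stop("degenerate input: filtered sensitivity is identically zero")
  out <- spectral_function(sensitivity$wavelength, v / max(v), "sensitivity")
  attr(out, "lambda_max") <- attr(sensitivity, "lambda_max")
  out
}

#' Pigment spectral sensitivity on a grid
#'
#' Builds the (optionally lens-filtered) normalised sensitivity for a
#' photopigment from the A1 template.
#'
#' @param pigment a [photopigment()].
#' @param grid wavelength grid, nm.
#' @param lens transmission `spectral_function`; used only if the pigment's
#'   `in_vivo` flag is set. Default: built-in [lens_transmission()] template.
#' @return A `spectral_function` of kind `"sensitivity"` with attribute
#'   `"pigment"` set to the pigment name.
#' @export
pigment_sensitivity <- function(pigment, grid = default_grid(), lens = NULL) {
  stopifnot(inherits(pigment, "photopigment"))
  s <- pigment_nomogram(pigment$lambda_max, grid)
  if (isTRUE(pigment$in_vivo)) {
    if (is.null(lens)) lens <- lens_transmission(grid)
    s <- apply_prereceptoral_filter(s, lens)
  }
  attr(s, "pigment") <- pigment$name
  s
}

#' Gaussian LED spectral power density
#'
#' Synthetic LED spectrum: a Gaussian of given peak wavelength and FWHM,
#' scaled so the trapezoidal integral over the grid equals `total_flux`
#' photons cm^-2 s^-1.
#'
#' @param peak_nm peak wavelength, nm.
#' @param fwhm_nm full width at half maximum, nm.
#' @param total_flux total photon flux, photons cm^-2 s^-1.
#' @param grid wavelength grid, nm.
#' @return A `spectral_function` of kind `"power_density"`.
#' @export
gaussian_spd <- function(peak_nm, fwhm_nm = 20, total_flux = 1e16,
                         grid = default_grid()) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  v <- dnorm(grid, peak_nm, sigma)
  v <- v * total_flux / pracma::trapz(grid, v)
  spectral_function(grid, v, "power_density")
}

#' Photoreceptor-effective irradiance
#'
#' @param flux photon flux, photons cm^-2 s^-1 (>= 0).
#' @param pigment pigment name the flux is effective for.
#' @param frame `"corneal"` or `"retinal"`.
#' @return An object of class `irradiance`.
#' @export
irradiance <- function(flux, pigment = NA_character_,
                       frame = c("corneal", "retinal")) {
  frame <- match.arg(frame)
  if (!is.numeric(flux) || length(flux) != 1L || !is.finite(flux) || flux < 0)
    stop("flux must be a single non-negative number")
  structure(list(flux = flux, pigment = pigment, frame = frame),
            class = "irradiance")
}

#' @export
print.irradiance <- function(x, ...) {
  cat(sprintf("<irradiance: %.4g photons/cm^2/s (%s, %s)%s>\n",
              x$flux, if (is.na(x$pigment)) "?" else x$pigment, x$frame,
              if (x$flux > 0) sprintf(", log10 = %.3f", log10(x$flux)) else ""))
  invisible(x)
}

#' Effective photon flux for a photopigment
#'
#' Multiplies a spectral power density by a normalised pigment sensitivity and
#' integrates across the spectrum by trapezoidal quadrature (exact for the
#' piecewise-linear representation of sampled spectra).
#'
#' @param spd a `spectral_function` of kind `"power_density"` in photon units.
#' @param sens a `spectral_function` of kind `"sensitivity"` on the same grid.
#' @param frame frame of the result; `"corneal"` by default.
#' @return An [irradiance()] in photons cm^-2 s^-1.
#' @export
effective_photon_flux <- function(spd, sens, frame = c("corneal", "retinal")) {
  stopifnot(inherits(spd, "spectral_function"), inherits(sens, "spectral_function"))
  if (spd$kind != "power_density" || sens$kind != "sensitivity")
    stop("expected a power density and a sensitivity")
  stop_if_grid_mismatch(spd, sens)
  frame <- match.arg(frame)
  flux <- pracma::trapz(spd$wavelength, spd$value * sens$value)
  irradiance(flux, pigment = attr(sens, "pigment") %||% NA_character_, frame = frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neutral-density attenuation
#'
#' Multiplies a flux, spectrum or stimulus by `10^(-nd)`. Attenuation composes
#' additively in optical density: `attenuate(x, a + b)` equals
#' `attenuate(attenuate(x, a), b)`.
#'
#' @param x a numeric flux, an [irradiance()], a power-density
#'   [spectral_function()], or a [stimulus_setting()] (whose `nd` increases).
#' @param nd decimal optical density, >= 0.
#' @return Same type as `x`.
#' @export
attenuate <- function(x, nd) {
  if (!is.numeric(nd) || length(nd) != 1L || !is.finite(nd) || nd < 0)
    stop("nd must be a single non-negative optical density")
  UseMethod("attenuate")
}

#' @export
attenuate.default <- function(x, nd) {
  if (!is.numeric(x)) stop("cannot attenuate objects of class ", class(x)[1])
  x * 10^(-nd)
}

#' @export
attenuate.irradiance <- function(x, nd) {
  x$flux <- x$flux * 10^(-nd)
  x
}

#' @export
attenuate.spectral_function <- function(x, nd) {
  if (x$kind != "power_density")
    stop("only power densities can be attenuated")
  x$value <- x$value * 10^(-nd)
  x
}

#' @export
attenuate.stimulus_setting <- function(x, nd) {
  x$nd <- x$nd + nd
  x
}

#' Convert retinal to corneal irradiance
#'
#' Multiplies a retinal-frame irradiance by the pupil-area / retinal-area
#' ratio, 0.5 for a fully dilated mouse pupil.
#'
#' @param x an [irradiance()] with `frame == "retinal"`.
#' @param factor conversion factor; 0.5 by default.
#' @return The corneal-frame irradiance.
#' @export
retinal_to_corneal <- function(x, factor = 0.5) {
  stopifnot(inherits(x, "irradiance"))
  if (x$frame != "retinal")
    stop("irradiance is already in the corneal frame")
  irradiance(x$flux * factor, pigment = x$pigment, frame = "corneal")
}

#' Log10 photon flux
#'
#' @param x a positive numeric flux or an [irradiance()].
#' @return log10 photons cm^-2 s^-1.
#' @export
log_flux <- function(x) {
  f <- if (inherits(x, "irradiance")) x$flux else x
  if (!is.numeric(f) || any(f <= 0))
    stop("log flux is only defined for strictly positive fluxes")
  log10(f)
}
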