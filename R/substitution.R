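# Silent-substitution design: two-primary stimulus settings, Michelson
# contrast bookkeeping, and the closed-form rod-silent step solver.

#' Two-primary silencing model
#'
#' Bundles the two LED primaries (unit-drive spectral power densities), the
#' photopigments and their in vivo sensitivities, and the 2 x 2 matrix of
#' pigment-effective photon fluxes per unit drive that all solvers work from.
#'
#' @param blue,yellow unit-drive SPDs (`spectral_function`, power density) of
#'   the short- and long-wavelength primary.
#' @param pigments named list of [photopigment()]s; defaults to mouse rod
#'   (498 nm) and melanopsin (480 nm).
#' @param lens transmission curve used for in vivo pigments; built-in
#'   template when `NULL`.
#' @param max_drive gamut bound per primary (drive weights must lie in
#'   `[0, max_drive]`).
#' @return An object of class `silencing_model` with the unit-flux matrix `M`
#'   (rows pigments, columns primaries).
#' @export
silencing_model <- function(blue, yellow,
                            pigments = list(rod = photopigment("rod"),
                                            melanopsin = photopigment("melanopsin")),
                            lens = NULL, max_drive = 1) {
  stopifnot(inherits(blue, "spectral_function"), inherits(yellow, "spectral_function"))
  stop_if_grid_mismatch(blue, yellow)
  grid <- blue$wavelength
  sens <- lapply(pigments, pigment_sensitivity, grid = grid, lens = lens)
  M <- vapply(list(blue = blue, yellow = yellow),
              function(spd) vapply(sens, function(s) effective_photon_flux(spd, s)$flux,
                                   numeric(1)),
              numeric(length(sens)))
  dimnames(M) <- list(names(pigments), c("blue", "yellow"))
  structure(list(grid = grid, primaries = list(blue = blue, yellow = yellow),
                 pigments = pigments, sensitivities = sens, M = M,
                 max_drive = max_drive),
            class = "silencing_model")
}

#' Default dLGN-style silencing model
#'
#' Gaussian LED fixture (peaks 438 and 575 nm, 20 nm FWHM, equal total photon
#' flux at unit drive) with mouse rod and melanopsin pigments.
#'
#' @param in_vivo apply lens filtering to the pigment sensitivities.
#' @param fwhm_nm LED full width at half maximum, nm.
#' @param total_flux total photon flux of each LED at unit drive.
#' @param grid wavelength grid.
#' @inheritParams silencing_model
#' @return A [silencing_model()].
#' @export
default_model <- function(in_vivo = TRUE, fwhm_nm = 20, total_flux = 1e16,
                          grid = default_grid(), max_drive = 1) {
  silencing_model(gaussian_spd(438, fwhm_nm, total_flux, grid),
                  gaussian_spd(575, fwhm_nm, total_flux, grid),
                  pigments = list(rod = photopigment("rod", in_vivo = in_vivo),
                                  melanopsin = photopigment("melanopsin", in_vivo = in_vivo)),
                  max_drive = max_drive)
}

#' @export
print.silencing_model <- function(x, ...) {
  cat("<silencing_model>\n  unit-drive effective fluxes (photons/cm^2/s):\n")
  print(signif(x$M, 4))
  cat(sprintf("  max_drive: %g\n", x$max_drive))
  invisible(x)
}

#' Stimulus setting: per-primary drives plus ND attenuation
#'
#' @param blue,yellow drive weights, each in `[0, max_drive]` of the model.
#' @param nd decimal neutral-density attenuation, >= 0.
#' @return An object of class `stimulus_setting`.
#' @export
stimulus_setting <- function(blue = 0, yellow = 0, nd = 0) {
  if (blue < 0 || yellow < 0) stop("drive weights must be non-negative")
  if (nd < 0) stop("nd must be non-negative")
  structure(list(blue = blue, yellow = yellow, nd = nd),
            class = "stimulus_setting")
}

#' @export
print.stimulus_setting <- function(x, ...) {
  cat(sprintf("<stimulus_setting: blue %.4g, yellow %.4g, ND %.2f>\n",
              x$blue, x$yellow, x$nd))
  invisible(x)
}

#' Pigment-effective flux of a stimulus setting
#'
#' `flux = 10^(-nd) * (blue * M[pigment, blue] + yellow * M[pigment, yellow])`;
#' linear in each drive weight.
#'
#' @param model a [silencing_model()].
#' @param setting a [stimulus_setting()].
#' @param pigment pigment name (row of the model's flux matrix).
#' @return An [irradiance()].
#' @export
setting_flux <- function(model, setting, pigment) {
  stopifnot(inherits(model, "silencing_model"), inherits(setting, "stimulus_setting"))
  if (!pigment %in% rownames(model$M))
    stop("unknown pigment: ", pigment)
  f <- (setting$blue * model$M[pigment, "blue"] +
        setting$yellow * model$M[pigment, "yellow"]) * 10^(-setting$nd)
  irradiance(f, pigment = pigment, frame = "corneal")
}

#' Michelson contrast
#'
#' `(step - background) / (step + background)` on effective photon flux;
#' antisymmetric under swapping arguments and bounded in \[-1, 1\].
#'
#' @param step_flux,bg_flux non-negative fluxes ([irradiance()] or numeric),
#'   not both zero.
#' @return Michelson fraction.
#' @export
michelson_contrast <- function(step_flux, bg_flux) {
  s <- if (inherits(step_flux, "irradiance")) step_flux$flux else step_flux
  b <- if (inherits(bg_flux, "irradiance")) bg_flux$flux else bg_flux
  if (s < 0 || b < 0) stop("fluxes must be non-negative")
  if (s + b == 0) stop("contrast is undefined when both fluxes are zero")
  (s - b) / (s + b)
}

#' Yellow-only background at a prescribed effective irradiance
#'
#' Convenience constructor: a background driven by the yellow primary alone,
#' scaled so its effective photon flux for `pigment` is `10^log10_flux`.
#'
#' @param model a [silencing_model()].
#' @param log10_flux target log10 photons cm^-2 s^-1 at ND 0.
#' @param pigment pigment the target applies to; melanopsin by default.
#' @return A [stimulus_setting()].
#' @export
background_for <- function(model, log10_flux, pigment = "melanopsin") {
  w <- 10^log10_flux / model$M[pigment, "yellow"]
  if (w > model$max_drive)
    stop(sprintf("target irradiance needs yellow drive %.3g > max_drive %g",
                 w, model$max_drive))
  stimulus_setting(blue = 0, yellow = w, nd = 0)
}

# Linear system core shared by the solver and the feasibility analysis:
# step weights are affine in the target flux ratio r, w(r) = w0 + r * w1.
silent_step_basis <- function(model, background, silenced, target) {
  M <- model$M
  for (p in c(silenced, target))
    if (!p %in% rownames(M)) stop("unknown pigment: ", p)
  if (silenced == target) stop("silenced and target pigment must differ")
  wbg <- c(background$blue, background$yellow)
  Fsil <- sum(M[silenced, ] * wbg)
  Ftar <- sum(M[target, ] * wbg)
  A <- M[c(silenced, target), , drop = FALSE]
  if (abs(det(A)) < 1e-12 * prod(sqrt(rowSums(A^2))))
    stop("degenerate primaries: pigment flux matrix is singular")
  list(w0 = solve(A, c(Fsil, 0)), w1 = solve(A, c(0, Ftar)),
       Fsil = Fsil, Ftar = Ftar)
}

#' Solve a silent-substitution step
#'
#' Finds per-primary drive weights for a 'step' stimulus that presents equal
#' effective photon flux to the silenced pigment as the background does, while
#' presenting a prescribed Michelson contrast `target_contrast` to the target
#' pigment. With two primaries the 2 x 2 linear system
#' \deqn{F_{sil}(step) = F_{sil}(bg), \quad
#'       F_{tar}(step) = F_{tar}(bg) (1 + c) / (1 - c)}
#' is solved in closed form. Weights must be physically realisable (within
#' `[0, max_drive]`), otherwise a gamut error names the limiting primary.
#'
#' @param model a [silencing_model()].
#' @param background background [stimulus_setting()].
#' @param silenced,target pigment names; defaults silence rods and target
#'   melanopsin.
#' @param target_contrast Michelson fraction in (-1, 1).
#' @param blue_gain per-preparation correction factor applied to the solved
#'   blue step weight (empirical 'online calibration'; default 1, i.e. none).
#' @return An object of class `stimulus_pair` carrying both settings,
#'   per-pigment fluxes and achieved contrasts. The silenced-pigment contrast
#'   is zero to <= 1e-9 and the target contrast within 1e-6 of the request
#'   (when `blue_gain = 1`).
#' @export
solve_silent_step <- function(model, background, silenced = "rod",
                              target = "melanopsin", target_contrast,
                              blue_gain = 1) {
  stopifnot(inherits(model, "silencing_model"),
            inherits(background, "stimulus_setting"))
  if (abs(target_contrast) >= 1)
    stop("target_contrast must lie strictly within (-1, 1)")
  bas <- silent_step_basis(model, background, silenced, target)
  r <- (1 + target_contrast) / (1 - target_contrast)
  w <- bas$w0 + r * bas$w1
  tol <- 1e-9 * max(model$max_drive, 1)
  for (i in seq_along(w)) {
    if (w[i] < -tol)
      stop(sprintf("gamut error: %s primary requires negative drive (%.3g) at contrast %g",
                   names(w)[i], w[i], target_contrast))
    if (w[i] > model$max_drive + tol)
      stop(sprintf("gamut error: %s primary requires drive %.3g > max_drive %g at contrast %g",
                   names(w)[i], w[i], model$max_drive, target_contrast))
  }
  w <- pmin(pmax(w, 0), model$max_drive)
  step <- stimulus_setting(blue = w[["blue"]] * blue_gain, yellow = w[["yellow"]],
                           nd = background$nd)
  pigs <- rownames(model$M)
  fl <- function(setting) lapply(setNames(pigs, pigs),
                                 function(p) setting_flux(model, setting, p))
  fluxes <- list(background = fl(background), step = fl(step))
  contrasts <- vapply(setNames(pigs, pigs), function(p)
    michelson_contrast(fluxes$step[[p]], fluxes$background[[p]]), numeric(1))
  structure(list(background = background, step = step,
                 silenced = silenced, target = target,
                 target_contrast = target_contrast, blue_gain = blue_gain,
                 fluxes = fluxes, contrasts = contrasts),
            class = "stimulus_pair")
}

#' @export
print.stimulus_pair <- function(x, ...) {
  cat(sprintf("<stimulus_pair: %s-silent, %s contrast %.4f (target %.4f)>\n",
              x$silenced, x$target, x$contrasts[[x$target]], x$target_contrast))
  cat(sprintf("  background: blue %.4g yellow %.4g ND %.2f\n",
              x$background$blue, x$background$yellow, x$background$nd))
  cat(sprintf("  step:       blue %.4g yellow %.4g ND %.2f\n",
              x$step$blue, x$step$yellow, x$step$nd))
  for (p in names(x$fluxes$background))
    cat(sprintf("  %-11s bg %.4g -> step %.4g photons/cm^2/s (contrast %+.2e)\n",
                paste0(p, ":"), x$fluxes$background[[p]]$flux,
                x$fluxes$step[[p]]$flux, x$contrasts[[p]]))
  invisible(x)
}

#' Maximum silent-substitution contrast within gamut
#'
#' Largest feasible `target_contrast` for [solve_silent_step()] under the
#' gamut constraints `0 <= weight <= max_drive`. Because the step weights are
#' affine in the flux ratio `r = (1 + c)/(1 - c)`, the bound is obtained in
#' closed form from the constraint lines.
#'
#' @inheritParams solve_silent_step
#' @return The largest feasible Michelson fraction (0 if the background is the
#'   unique feasible point).
#' @export
max_silent_contrast <- function(model, background, silenced = "rod",
                                target = "melanopsin") {
  bas <- silent_step_basis(model, background, silenced, target)
  if (bas$Ftar == 0) return(0)
  r_hi <- Inf
  for (i in 1:2) {
    w0 <- bas$w0[i]; w1 <- bas$w1[i]
    if (w1 > 0) r_hi <- min(r_hi, (model$max_drive - w0) / w1)
    else if (w1 < 0) r_hi <- min(r_hi, (0 - w0) / w1)
    else if (w0 < 0 || w0 > model$max_drive) return(0)
  }
  if (!is.finite(r_hi) || r_hi <= 1) return(0)
  (r_hi - 1) / (r_hi + 1)
}

#' Melanopsin-isolating contrast series
#'
#' One rod-silent stimulus pair per requested melanopsin contrast. Across
#' descending contrasts the step mixes in increasing yellow and decreasing
#' blue drive.
#'
#' @inheritParams solve_silent_step
#' @param targets Michelson fractions; default the canonical series 71, 60, 51,
#'   38, 32, 21 and 11%.
#' @return A list of `stimulus_pair` objects, named by percent contrast.
#' @export
contrast_series <- function(model, background,
                            targets = c(0.71, 0.60, 0.51, 0.38, 0.32, 0.21, 0.11),
                            silenced = "rod", target = "melanopsin",
                            blue_gain = 1) {
  pairs <- lapply(targets, function(ct)
    tryCatch(solve_silent_step(model, background, silenced, target, ct, blue_gain),
             error = function(e)
               stop(sprintf("contrast %.3g infeasible: %s", ct, conditionMessage(e)),
                    call. = FALSE)))
  names(pairs) <- sprintf("c%02d", round(100 * targets))
  pairs
}

#' Rod-contrast control series
#'
#' Melanopsin-isoluminant pairs presenting prescribed rod contrasts, used to
#' establish the lower bound of detectable rod contrast (4, 15 and 30% in the
#' calibration experiments).
#'
#' @inheritParams solve_silent_step
#' @param targets rod Michelson fractions.
#' @return A list of `stimulus_pair` objects.
#' @export
rod_contrast_control <- function(model, background,
                                 targets = c(0.04, 0.15, 0.30)) {
  contrast_series(model, background, targets,
                  silenced = "melanopsin", target = "rod")
}
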