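# Synthetic retina / dLGN: phenomenological firing-rate models for rod- and
# melanopsin-driven units, and inhomogeneous Poisson spike generation.
#
# The rate models are deliberately simple. Melanopsin drive is
# threshold-linear in log irradiance passed through an asymmetric first-order
# filter (slow rise, slower decay); an exponentially weighted recent-light
# average elevates the threshold (light adaptation). Rod drive is a transient
# response to Michelson contrast between the instantaneous rod-effective flux
# and a running background estimate, with a hard contrast threshold, so
# rod-silent transitions evoke exactly zero rod modulation.

#' Parameters of a simulated unit
#'
#' @param unit_class `"mel_stepper"` (melanopsin step response plus rod
#'   transients), `"irradiance_tracker"` (slowly follows the background
#'   irradiance ramp), `"rod_only"`, or `"null"` (baseline only).
#' @param baseline_hz spontaneous firing rate, Hz.
#' @param rod_gain rod response gain, Hz per unit Michelson contrast.
#' @param rod_tau_s time constant of the rod background estimate, s; sets the
#'   transient decay of rod step responses.
#' @param rod_contrast_threshold contrasts below this magnitude evoke no rod
#'   response (default 0.10: 4% controls are sub-, 15% supra-threshold).
#' @param mel_gain melanopsin drive gain, Hz per log unit above threshold.
#' @param mel_tau_on_s,mel_tau_off_s rise / decay time constants of the
#'   melanopsin response filter, s. Defaults (5.4 and 32 s) are calibrated so
#'   the 1-SD latency statistic on default-gain responses lands near the
#'   measured pre-drug latency means (4.5 s onset, 18 s offset).
#' @param mel_threshold_log baseline melanopsin threshold, log10 photons
#'   cm^-2 s^-1 (default 12.6; see the methods vignette).
#' @param adapt_gain fraction in \[0, 1\] by which recent supra-threshold
#'   light history elevates the melanopsin threshold (0 = no adaptation).
#' @param adapt_tau_s time constant of the light-history average, s.
#' @param tracker_tau_s filter time constant of irradiance-tracker units, s.
#' @param reliability_p probability that a trial expresses the evoked
#'   response.
#' @param rate_floor lower bound on the firing rate, Hz.
#' @return An object of class `unit_params`.
#' @export
unit_params <- function(unit_class = c("mel_stepper", "irradiance_tracker",
                                       "rod_only", "null"),
                        baseline_hz = 5, rod_gain = 40, rod_tau_s = 5,
                        rod_contrast_threshold = 0.10,
                        mel_gain = 2.5, mel_tau_on_s = 5.4, mel_tau_off_s = 32,
                        mel_threshold_log = 12.6, adapt_gain = 0,
                        adapt_tau_s = 600, tracker_tau_s = 20,
                        reliability_p = 1, rate_floor = 0) {
  unit_class <- match.arg(unit_class)
  p <- list(unit_class = unit_class, baseline_hz = baseline_hz,
            rod_gain = rod_gain, rod_tau_s = rod_tau_s,
            rod_contrast_threshold = rod_contrast_threshold,
            mel_gain = mel_gain, mel_tau_on_s = mel_tau_on_s,
            mel_tau_off_s = mel_tau_off_s,
            mel_threshold_log = mel_threshold_log,
            adapt_gain = adapt_gain, adapt_tau_s = adapt_tau_s,
            tracker_tau_s = tracker_tau_s,
            reliability_p = reliability_p, rate_floor = rate_floor,
            prep = NA_character_)
  for (f in c("rod_tau_s", "mel_tau_on_s", "mel_tau_off_s", "adapt_tau_s",
              "tracker_tau_s"))
    if (p[[f]] <= 0) stop(f, " must be positive")
  for (f in c("baseline_hz", "rod_gain", "mel_gain", "rate_floor"))
    if (p[[f]] < 0) stop(f, " must be non-negative")
  if (reliability_p < 0 || reliability_p > 1 || adapt_gain < 0 || adapt_gain > 1)
    stop("probabilities and adapt_gain must lie in [0, 1]")
  structure(p, class = "unit_params")
}

#' Apply a preparation mode to unit parameters
#'
#' Adjusts kinetics and gains for the recording preparation. Idempotent: a
#' preparation already applied leaves the parameters unchanged.
#'
#' * `cnga3_dlgn`: in vivo coneless dLGN; light adaptation enabled
#'   (`adapt_gain` 0.8).
#' * `cnga3_retina`: coneless retina in vitro; no threshold adaptation.
#' * `blockade`: glutamatergic blockade of the coneless retina; rod input
#'   abolished, baseline reduced (x 0.6), melanopsin kinetics slowed (taus
#'   inflated to >= 9 / 67 s so the 1-SD latencies land near the measured
#'   post-drug means, 7.5 s onset / 38 s offset).
#' * `rdcl_retina`: rodless + coneless retina; melanopsin only, very sluggish
#'   (taus >= 6.9 / 89 s), unreliable (`reliability_p` <= 0.6).
#'
#' @param p a [unit_params()] object.
#' @param prep preparation name.
#' @return Modified `unit_params`.
#' @export
apply_prep <- function(p, prep = c("cnga3_dlgn", "cnga3_retina",
                                   "rdcl_retina", "blockade")) {
  stopifnot(inherits(p, "unit_params"))
  prep <- match.arg(prep)
  if (identical(p$prep, prep)) return(p)
  if (prep == "cnga3_dlgn") {
    p$adapt_gain <- 0.8
  } else if (prep == "cnga3_retina") {
    p$adapt_gain <- 0
  } else if (prep == "blockade") {
    p$rod_gain <- 0
    p$baseline_hz <- p$baseline_hz * 0.6
    p$mel_tau_on_s <- max(p$mel_tau_on_s, 9)
    p$mel_tau_off_s <- max(p$mel_tau_off_s, 67)
    p$adapt_gain <- 0
  } else if (prep == "rdcl_retina") {
    p$rod_gain <- 0
    p$mel_tau_on_s <- max(p$mel_tau_on_s, 6.9)
    p$mel_tau_off_s <- max(p$mel_tau_off_s, 89)
    p$reliability_p <- min(p$reliability_p, 0.6)
    p$adapt_gain <- 0
  }
  p$prep <- prep
  p
}

# log10 flux with darkness mapped far below any threshold
safe_log10 <- function(flux) log10(pmax(flux, 1))

#' Melanopsin-driven firing-rate component
#'
#' Threshold-linear drive in log melanopsin-effective irradiance,
#' `u = mel_gain * max(0, log10(flux) - theta(t))`, filtered by an asymmetric
#' first-order filter (`mel_tau_on_s` rising, `mel_tau_off_s` falling). The
#' adaptation state elevates the threshold towards
#' `theta_base + adapt_gain * (recent mean log flux - theta_base)` with time
#' constant `adapt_tau_s`, so thresholds are raised after bright exposure.
#'
#' @param trace a [render_trace()] result including a melanopsin column.
#' @param p a [unit_params()] object.
#' @param gate optional 0/1 vector gating the drive (trial reliability).
#' @return Firing-rate modulation time series, Hz (>= 0).
#' @export
mel_drive <- function(trace, p, gate = NULL) {
  l <- safe_log10(trace$flux[, "melanopsin"])
  m <- ema_cpp(l, trace$dt, p$adapt_tau_s, l[1])
  theta <- p$mel_threshold_log + p$adapt_gain * pmax(0, m - p$mel_threshold_log)
  u <- p$mel_gain * pmax(0, l - theta)
  if (!is.null(gate)) u <- u * gate
  asym_filter_cpp(u, trace$dt, p$mel_tau_on_s, p$mel_tau_off_s, u[1])
}

#' Rod-driven firing-rate component
#'
#' Transient response to the Michelson contrast between the instantaneous
#' rod-effective flux and a running background estimate (exponential moving
#' average, time constant `rod_tau_s`). Contrasts below
#' `rod_contrast_threshold` in magnitude evoke no response, so rod-silent
#' transitions produce exactly zero and slow ND ramps stay sub-threshold.
#'
#' @inheritParams mel_drive
#' @return Signed firing-rate modulation, Hz (negative for negative
#'   contrast; the unit rate is floored later).
#' @export
rod_drive <- function(trace, p, gate = NULL) {
  f <- trace$flux[, "rod"]
  b <- ema_cpp(f, trace$dt, p$rod_tau_s, f[1])
  tot <- f + b
  ctr <- ifelse(tot > 0, (f - b) / tot, 0)
  ctr[abs(ctr) < p$rod_contrast_threshold] <- 0
  d <- p$rod_gain * ctr
  if (!is.null(gate)) d <- d * gate
  d
}

# Irradiance-tracker drive: slow threshold-linear coding of the
# spectrally-neutral background, computed on the rod-effective flux so that
# rod-silent melanopsin steps are invisible to trackers by construction.
tracker_drive <- function(trace, p, gate = NULL) {
  l <- safe_log10(trace$flux[, "rod"])
  u <- p$mel_gain * pmax(0, l - p$mel_threshold_log)
  if (!is.null(gate)) u <- u * gate
  asym_filter_cpp(u, trace$dt, p$tracker_tau_s, p$tracker_tau_s, u[1])
}

#' Deterministic firing rate of a unit over a protocol
#'
#' Combines baseline and class-appropriate drive components, floored at
#' `rate_floor`.
#'
#' @inheritParams mel_drive
#' @return Non-negative firing-rate series, Hz.
#' @export
unit_rate <- function(trace, p, gate = NULL) {
  n <- length(trace$time)
  r <- rep(p$baseline_hz, n)
  r <- r + switch(p$unit_class,
    mel_stepper = mel_drive(trace, p, gate) + rod_drive(trace, p, gate),
    irradiance_tracker = tracker_drive(trace, p, gate),
    rod_only = rod_drive(trace, p, gate),
    null = 0)
  pmax(r, p$rate_floor)
}

#' Sample an inhomogeneous Poisson spike train
#'
#' The rate series is piecewise constant over `dt` bins, so binwise Poisson
#' counts with uniform placement within each bin sample the inhomogeneous
#' Poisson process exactly: counts in any window are Poisson with mean equal
#' to the integrated rate.
#'
#' @param rate non-negative firing-rate series, Hz.
#' @param dt bin width, s.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param t0 time of the first bin's left edge, s.
#' @return Sorted spike times, s.
#' @export
sample_spikes <- function(rate, dt, seed = NULL, t0 = 0) {
  if (any(rate < 0) || any(!is.finite(rate)))
    stop("rate must be finite and non-negative")
  draw <- function() {
    counts <- rpois(length(rate), rate * dt)
    idx <- rep.int(seq_along(rate), counts)
    sort((idx - 1) * dt + runif(length(idx)) * dt + t0)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Population specification
#'
#' @param n_units number of units.
#' @param class_fractions named fractions summing to 1; defaults follow the
#'   observed dLGN proportions (28% steppers, 17% trackers, 35% rod-only,
#'   20% unresponsive).
#' @param prep preparation mode, see [apply_prep()].
#' @param seed master seed for parameter jitter, trial reliability and
#'   spiking.
#' @param param_jitter relative (lognormal) SD of per-unit parameter jitter.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_units,
                            class_fractions = c(mel_stepper = 0.28,
                                                irradiance_tracker = 0.17,
                                                rod_only = 0.35, null = 0.20),
                            prep = "cnga3_dlgn", seed = 1, param_jitter = 0.2) {
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must be non-negative and sum to 1")
  structure(list(n_units = n_units, class_fractions = class_fractions,
                 prep = prep, seed = seed, param_jitter = param_jitter),
            class = "population_spec")
}

#' Allocate unit classes by largest remainder
#'
#' Deterministic integer allocation of `n` units to classes: floors of
#' `n * fraction`, remaining units to the largest fractional remainders.
#'
#' @param n number of units.
#' @param fractions named fractions summing to 1.
#' @return Character vector of class labels, length `n`.
#' @export
allocate_classes <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- round(n - sum(base))
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  rep(names(fractions), times = base)
}

#' Draw a population of unit parameters
#'
#' Classes are allocated deterministically ([allocate_classes()]); gains,
#' baseline and time constants receive multiplicative lognormal jitter with
#' relative SD `param_jitter`; the preparation mode is then applied.
#'
#' @param spec a [population_spec()].
#' @return List of [unit_params()], names `u001`, `u002`, ...
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  classes <- allocate_classes(spec$n_units, spec$class_fractions)
  jfields <- c("baseline_hz", "rod_gain", "mel_gain", "mel_tau_on_s",
               "mel_tau_off_s", "rod_tau_s", "tracker_tau_s")
  with_seed(derive_seed(spec$seed, "population"), {
    lapply(setNames(seq_len(spec$n_units),
                    sprintf("u%03d", seq_len(spec$n_units))), function(i) {
      p <- unit_params(unit_class = classes[i])
      for (f in jfields)
        p[[f]] <- p[[f]] * exp(rnorm(1, 0, spec$param_jitter))
      apply_prep(p, spec$prep)
    })
  })
}

#' Simulate a spike dataset over a protocol
#'
#' Renders the protocol to per-pigment irradiance traces, computes each
#' unit's deterministic rate (with per-trial Bernoulli response expression
#' gating the step/flash drive), and samples inhomogeneous Poisson spike
#' trains. Fully reproducible given the specification seed and protocol.
#'
#' @param protocol a `protocol`.
#' @param spec a [population_spec()].
#' @param model a [silencing_model()].
#' @param dt simulation time step, s (0.1 s default; use finer steps for
#'   flicker protocols).
#' @param population optional pre-drawn [sample_population()] result, so the
#'   same units can be simulated across several protocols.
#' @return An object of class `spike_dataset`: `spikes` (named list of spike
#'   time vectors), `truth` (per-unit ground-truth table), `protocol`, `dt`.
#' @export
simulate_dataset <- function(protocol, spec, model, dt = 0.1,
                             population = NULL) {
  stopifnot(inherits(protocol, "protocol"), inherits(spec, "population_spec"))
  trace <- render_trace(protocol, model, dt)
  if (is.null(population)) population <- sample_population(spec)
  ep <- protocol$epochs
  stim <- which(ep$kind %in% c("step", "flash"))
  edges <- c(0, cumsum(ep$duration))
  n <- length(trace$time)
  spikes <- vector("list", length(population))
  names(spikes) <- names(population)
  with_seed(derive_seed(spec$seed, paste0("spikes_", protocol$metadata$id %||% "p")), {
    for (u in names(population)) {
      p <- population[[u]]
      gate <- NULL
      if (p$reliability_p < 1 && length(stim)) {
        gate <- rep(1, n)
        expressed <- rbinom(length(stim), 1, p$reliability_p)
        for (k in seq_along(stim)) {
          if (expressed[k] == 0) {
            i0 <- floor(edges[stim[k]] / dt) + 1
            i1 <- min(n, ceiling(edges[stim[k] + 1] / dt))
            gate[i0:i1] <- 0
          }
        }
      }
      rate <- unit_rate(trace, p, gate)
      spikes[[u]] <- sample_spikes(rate, dt)
    }
  })
  truth <- data.frame(unit_id = names(population),
                      class = vapply(population, `[[`, character(1), "unit_class"),
                      baseline_hz = vapply(population, `[[`, numeric(1), "baseline_hz"),
                      mel_gain = vapply(population, `[[`, numeric(1), "mel_gain"),
                      reliability_p = vapply(population, `[[`, numeric(1), "reliability_p"),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(spikes = spikes, truth = truth, protocol = protocol,
                 dt = dt, prep = spec$prep),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  nsp <- sum(vapply(x$spikes, length, integer(1)))
  cat(sprintf("<spike_dataset: %d units, %d spikes, %.1f min of %s>\n",
              length(x$spikes), nsp, protocol_duration(x$protocol) / 60,
              x$protocol$metadata$id %||% "protocol"))
  if (!is.null(x$truth)) print(table(x$truth$class))
  invisible(x)
}
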