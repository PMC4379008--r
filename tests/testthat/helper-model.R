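# Shared fixtures, built in code once per test run.

the_model <- default_model()
the_bg <- background_for(the_model, 14.3)          # ND0 dLGN background
the_series <- contrast_series(the_model, the_bg)   # 71 ... 11% pairs

# Independent 1-D enumeration oracle for the maximum rod-silent melanopsin
# contrast: scan blue step weights, solve the yellow weight from the scalar
# rod-isoluminance equation, and take the best in-gamut melanopsin contrast.
grid_max_contrast <- function(model, bg, n = 1e4) {
  M <- model$M
  Fr <- bg$blue * M["rod", "blue"] + bg$yellow * M["rod", "yellow"]
  Fm <- bg$blue * M["melanopsin", "blue"] + bg$yellow * M["melanopsin", "yellow"]
  b <- seq(0, model$max_drive, length.out = n)
  y <- (Fr - b * M["rod", "blue"]) / M["rod", "yellow"]
  ok <- y >= 0 & y <= model$max_drive
  fm <- b * M["melanopsin", "blue"] + y * M["melanopsin", "yellow"]
  max((fm[ok] - Fm) / (fm[ok] + Fm))
}

# Noiseless binned rate with a first-order-filter response, parameterised so
# the 1-SD crossing times equal the requested latencies. The baseline gets a
# deterministic +/- dither whose sample SD defines the threshold line; the
# filter time constants are then solved from the analytic crossing formulas
# t_on = tau_on * ln(g / (g - T')), t_off = tau_off * ln(A / T').
make_filter_rate <- function(onset_target, offset_target, gain = 2,
                             base = 5, dither = 1, bin_s = 0.1,
                             baseline_s = 30, step_s = 30, tail_s = 60) {
  centres <- seq(-baseline_s + bin_s / 2, step_s + tail_s - bin_s / 2, by = bin_s)
  nb <- sum(centres < 0)
  bl <- base + dither * rep_len(c(1, -1), nb)
  thr_prime <- sd(bl)                      # what the estimator will compute
  stopifnot(gain > thr_prime)
  tau_on <- onset_target / log(gain / (gain - thr_prime))
  rise <- gain * (1 - exp(-centres[centres >= 0 & centres < step_s] / tau_on))
  A <- gain * (1 - exp(-step_s / tau_on))
  stopifnot(A > thr_prime)
  tau_off <- offset_target / log(A / thr_prime)
  toff <- centres[centres >= step_s] - step_s
  decay <- A * exp(-toff / tau_off)
  rate <- c(bl, base + rise, base + decay)
  list(estimate = rate_estimate(centres, rate, bin_s),
       onset = onset_target, offset = offset_target,
       baseline_s = baseline_s, step_s = step_s)
}
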