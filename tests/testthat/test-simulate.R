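# Constructs a bare stimulus_trace for unit-level drive tests.
make_trace <- function(mel_log, rod_flux = NULL, dt = 0.1) {
  n <- length(mel_log)
  flux <- cbind(rod = rod_flux %||% rep(1e14, n), melanopsin = 10^mel_log)
  structure(list(time = (seq_len(n) - 1) * dt, dt = dt, flux = flux,
                 nd = rep(0, n), epoch = rep(1L, n)),
            class = "stimulus_trace")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("melanopsin drive is zero below threshold and reaches the analytic asymptote", {
  p <- unit_params(unit_class = "mel_stepper", adapt_gain = 0)
  sub <- make_trace(rep(11.5, 1000))
  expect_true(all(mel_drive(sub, p) == 0))
  # step 14.04 -> 14.3 held long: asymptotic increment mel_gain * 0.26
  tr <- make_trace(c(rep(14.04, 4000), rep(14.30, 4000)))
  d <- mel_drive(tr, p)
  pre <- d[4000]
  expect_equal(d[8000] - pre, p$mel_gain * 0.26, tolerance = 1e-3)
  # time to (1 - 1/e) of the increment is tau_on, within one sample
  target <- pre + (1 - exp(-1)) * (d[8000] - pre)
  t_hit <- (which(d[4001:8000] >= target)[1]) * tr$dt
  expect_lt(abs(t_hit - p$mel_tau_on_s), 2 * tr$dt)
})

test_that("adaptation elevates the threshold after bright exposure", {
  p <- unit_params(unit_class = "mel_stepper", adapt_gain = 0.8)
  # after a bright hold, the same level drives less than without the history
  lvl <- 14.0
  bright_first <- make_trace(c(rep(14.3, 12000), rep(lvl, 2000)))
  dim_only <- make_trace(rep(lvl, 14000))
  d1 <- mel_drive(bright_first, p)
  d2 <- mel_drive(dim_only, p)
  expect_lt(d1[14000], d2[14000] - 0.3)
})

test_that("rod drive is exactly zero for rod-silent steps and thresholds contrast", {
  p1 <- build_protocol1(the_series[c("c71", "c32")], repeats = 2, isi_s = 60,
                        adaptation_s = 60, seed = 1)
  tr <- render_trace(p1, the_model, dt = 0.1)
  p <- unit_params(unit_class = "rod_only")
  expect_true(all(rod_drive(tr, p) == 0))
  # a supra-threshold step drives a transient; doubling the gain doubles it
  f <- c(rep(1e13, 600), rep(1.5e13, 300), rep(1e13, 600))
  st <- make_trace(rep(10, 1500), rod_flux = f)
  d1 <- rod_drive(st, p)
  expect_gt(max(d1), 0)
  p2 <- p; p2$rod_gain <- 2 * p$rod_gain
  expect_equal(max(rod_drive(st, p2)), 2 * max(d1), tolerance = 1e-9)
  # sub-threshold contrast (4%) evokes nothing
  f4 <- c(rep(1e13, 600), rep(1e13 * 1.04 / 0.96, 300), rep(1e13, 600))
  st4 <- make_trace(rep(10, 1500), rod_flux = f4)
  expect_true(all(rod_drive(st4, p) == 0))
})

test_that("preparation modes adjust parameters idempotently", {
  p <- unit_params(unit_class = "mel_stepper")
  b1 <- apply_prep(p, "blockade")
  expect_equal(b1$rod_gain, 0)
  expect_equal(b1$baseline_hz, 0.6 * p$baseline_hz)
  expect_gt(b1$mel_tau_on_s, p$mel_tau_on_s)
  expect_gt(b1$mel_tau_off_s, p$mel_tau_off_s)
  expect_identical(apply_prep(b1, "blockade"), b1)
  r1 <- apply_prep(p, "rdcl_retina")
  expect_equal(r1$rod_gain, 0)
  expect_equal(r1$reliability_p, 0.6)
  expect_gt(r1$mel_tau_off_s, b1$mel_tau_off_s)
  d1 <- apply_prep(p, "cnga3_dlgn")
  expect_gt(d1$adapt_gain, 0)
  expect_equal(apply_prep(p, "cnga3_retina")$adapt_gain, 0)
})

test_that("spike sampling is Poisson with the integrated rate and seed-reproducible", {
  expect_length(sample_spikes(rep(0, 100), 0.1, seed = 1), 0)
  expect_identical(sample_spikes(rep(10, 1000), 0.1, seed = 9),
                   sample_spikes(rep(10, 1000), 0.1, seed = 9))
  expect_error(sample_spikes(c(1, -1), 0.1), "non-negative")
  # 10 Hz for 100 s over 200 seeds: mean count within 3 SE of 1000
  counts <- vapply(1:200, function(s)
    length(sample_spikes(rep(10, 1000), 0.1, seed = s)), numeric(1))
  se <- sqrt(1000 / 200)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("rescaled inter-spike intervals of an inhomogeneous train are Exp(1)", {
  dt <- 0.01
  rate <- 8 + 5 * sin(2 * pi * (1:20000) * dt / 7)
  sp <- sample_spikes(rate, dt, seed = 21)
  Lambda <- approx(c(0, (1:20000) * dt), c(0, cumsum(rate * dt)), xout = sp)$y
  isis <- diff(Lambda)
  ks <- suppressWarnings(stats::ks.test(isis, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("class allocation uses largest remainders deterministically", {
  a <- allocate_classes(100, c(mel_stepper = 0.28, irradiance_tracker = 0.17,
                               rod_only = 0.35, null = 0.20))
  expect_equal(unname(table(a)[c("mel_stepper", "irradiance_tracker",
                                 "rod_only", "null")]),
               c(28L, 17L, 35L, 20L), ignore_attr = TRUE)
  b <- allocate_classes(7, c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(unname(table(b)[c("a", "b", "c")]), c(4L, 2L, 1L),
               ignore_attr = TRUE)
})

test_that("null units fire at baseline and datasets are reproducible", {
  p1 <- build_protocol1(the_series["c71"], repeats = 2, isi_s = 60,
                        adaptation_s = 60, seed = 1)
  tr <- render_trace(p1, the_model, dt = 0.1)
  pn <- unit_params(unit_class = "null", baseline_hz = 4)
  expect_true(all(unit_rate(tr, pn) == 4))
  spec <- population_spec(6, seed = 12)
  d1 <- simulate_dataset(p1, spec, the_model)
  d2 <- simulate_dataset(p1, spec, the_model)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$truth, d2$truth)
  expect_equal(nrow(d1$truth), 6)
  # spikes lie within the protocol and are strictly increasing per unit
  for (u in names(d1$spikes)) {
    sp <- d1$spikes[[u]]
    expect_true(all(sp >= 0 & sp <= protocol_duration(p1)))
    expect_true(all(diff(sp) > 0))
  }
})

test_that("down-arm thresholds exceed up-arm thresholds increasingly with adapt_gain", {
  p2 <- build_protocol2(the_series[["c71"]])
  tr <- render_trace(p2, the_model, dt = 0.2)
  on <- epoch_onsets(p2, "step")
  lev <- ramp_step_levels(p2, the_model, the_bg)
  eff_threshold <- function(arm, rate) {
    sel <- which(on$arm == arm)
    d <- vapply(sel, function(i) {
      i0 <- round(on$t_on[i] / 0.2)
      mean(rate[i0:(i0 + 150)]) - mean(rate[(i0 - 50):i0])
    }, numeric(1))
    L <- lev$level_log[sel]
    o <- order(L); L <- L[o]; d <- d[o]
    i <- which(d > 0.2)[1]
    if (is.na(i) || i == 1) return(L[1])
    # linear interpolation of the 0.2 Hz crossing
    L[i - 1] + (0.2 - d[i - 1]) / (d[i] - d[i - 1]) * (L[i] - L[i - 1])
  }
  gaps <- vapply(c(0, 0.4, 0.8), function(g) {
    p <- unit_params(unit_class = "mel_stepper", adapt_gain = g)
    r <- unit_rate(tr, p)
    eff_threshold("down", r) - eff_threshold("up", r)
  }, numeric(1))
  expect_lt(abs(gaps[1]), 0.05)
  expect_gt(gaps[2], gaps[1] + 0.05)
  expect_gt(gaps[3], gaps[2] + 0.05)
})

test_that("trial reliability gates the evoked response", {
  p1 <- build_protocol1(the_series["c71"], repeats = 10, isi_s = 60,
                        adaptation_s = 60, seed = 2)
  spec_lo <- population_spec(4, class_fractions = c(mel_stepper = 1,
                                                    irradiance_tracker = 0,
                                                    rod_only = 0, null = 0),
                             prep = "rdcl_retina", seed = 5)
  ds <- simulate_dataset(p1, spec_lo, the_model)
  on <- epoch_onsets(p1, "step")
  ar <- aligned_rates(ds, on$t_on, baseline_s = 30, response_s = 30)
  # with reliability 0.6 some trials must be near-null while others respond
  deltas <- ar$step_hz - ar$baseline_hz
  expect_gt(max(deltas), 0.8)
  expect_lt(sort(deltas)[3], 0.6)
})
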