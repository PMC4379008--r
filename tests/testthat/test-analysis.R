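test_that("psth counts spikes into rate bins with SEM over trials", {
  # one spike per trial in one bin, 10 trials, 0.1 s bins -> 10 Hz there
  events <- seq(0, 900, by = 100)
  spikes <- sort(events + 0.55)
  pe <- psth(spikes, events, window = c(-1, 2), bin_s = 0.1)
  expect_equal(pe$rate[pe$centre == 0.55], 10)
  expect_equal(sum(pe$rate > 0), 1)
  expect_equal(pe$sem[pe$centre == 0.55], 0)  # identical across trials
  # empty trains give an all-zero PSTH
  p0 <- psth(numeric(0), events, window = c(-1, 2), bin_s = 0.1)
  expect_true(all(p0$rate == 0))
  # a regular 10 Hz train is flat at 10 Hz up to quantisation
  reg <- seq(0.05, 1000, by = 0.1)
  pr <- psth(reg, events, window = c(0, 10), bin_s = 0.5)
  expect_true(all(abs(pr$rate - 10) <= 2))
  expect_equal(mean(pr$rate), 10, tolerance = 0.01)
})

test_that("trial bin counts normalise to a unit maximum and flag all-zero epochs", {
  events <- c(100, 200, 300)
  reg <- sort(unlist(lapply(events, function(e) e + seq(-29.9, 29.9, by = 0.25))))
  m <- trial_bin_count(reg, events, window = c(-30, 30), bin_s = 5)
  expect_true(all(abs(m - 4) < 1e-9))
  mn <- trial_bin_count(reg, events, window = c(-30, 30), bin_s = 5,
                        normalise = TRUE)
  expect_equal(max(mn), 1)
  z <- trial_bin_count(numeric(0), events, window = c(-30, 30), bin_s = 5,
                       normalise = TRUE)
  expect_true(all(z == 0))
  expect_true(attr(z, "all_zero"))
})

test_that("responder classification handles degenerate and planted cases", {
  flat <- data.frame(unit_id = "u1", trial = 1:6,
                     baseline_hz = rep(4, 6), step_hz = rep(4, 6))
  r <- classify_responsive(flat)
  expect_equal(r$p_value, 1)
  expect_false(r$responsive)
  # planted effect is detected; decreases are rejected under direction = increase
  set.seed(101)
  up <- data.frame(unit_id = "u2", trial = 1:14,
                   baseline_hz = rpois(14, 150) / 30,
                   step_hz = rpois(14, 210) / 30)
  expect_true(classify_responsive(up)$responsive)
  down <- up; down$step_hz <- rpois(14, 90) / 30
  expect_false(classify_responsive(down, direction = "increase")$responsive)
  expect_true(classify_responsive(down, direction = "decrease")$responsive)
})

test_that("delta firing rate is the step-minus-baseline mean and flips sign on swap", {
  d <- data.frame(unit_id = "u1", trial = 1:5,
                  baseline_hz = c(5, 4, 6, 5, 5), step_hz = c(7, 6, 8, 7, 7))
  expect_equal(delta_firing_rate(d)$delta_hz, 2)
  swapped <- data.frame(unit_id = "u1", trial = 1:5,
                        baseline_hz = d$step_hz, step_hz = d$baseline_hz)
  expect_equal(delta_firing_rate(swapped)$delta_hz, -2)
})

test_that("latency estimator is exact within one bin on noiseless filter rates", {
  for (tgt in list(c(2.0, 8.0), c(4.48, 18.30), c(7.48, 38.21))) {
    fr <- make_filter_rate(tgt[1], tgt[2], gain = 2, tail_s = 80)
    lat <- response_latencies(fr$estimate, baseline_window = c(-30, 0),
                              onset_s = 0, offset_s = 30)
    expect_lt(abs(lat$onset_s - tgt[1]), 0.1 + 1e-9)
    expect_lt(abs(lat$offset_s - tgt[2]), 0.1 + 1e-9)
    expect_false(lat$degenerate)
  }
})

test_that("latencies are NA without a crossing and flagged when the baseline is flat", {
  centres <- seq(-9.95, 29.95, by = 0.1)
  flat <- rate_estimate(centres, rep(5, length(centres)), 0.1)
  lat <- response_latencies(flat, baseline_window = c(-10, 0), offset_s = 10)
  expect_true(is.na(lat$onset_s))
  expect_true(lat$degenerate)
  # degenerate threshold equals the baseline mean; a clean step crosses at onset
  stepr <- rate_estimate(centres, ifelse(centres >= 2, 9, 5), 0.1)
  lat2 <- response_latencies(stepr, baseline_window = c(-10, 0), offset_s = 10)
  expect_true(lat2$degenerate)
  expect_equal(lat2$onset_s, 2.05, tolerance = 1e-9)
})

test_that("latency estimate is unbiased within a bin over noisy seeds", {
  base <- 5; gain <- 4; tau_on <- 3; n_trials <- 200; bin_s <- 0.5
  events <- seq(100, 100 * n_trials, by = 100)
  rate_fun <- function(t) {
    r <- rep(base, length(t))
    on <- t %% 100 >= 60 & t %% 100 < 90
    r[on] <- base + gain * (1 - exp(-((t[on] %% 100) - 60) / tau_on))
    r
  }
  tt <- seq(0.05, 100 * n_trials, by = 0.1)
  rr <- rate_fun(tt)
  err <- vapply(1:100, function(s) {
    sp <- sample_spikes(rr, 0.1, seed = s)
    pe <- psth(sp, events + 60, window = c(-30, 40), bin_s = bin_s)
    lat <- response_latencies(pe, baseline_window = c(-30, 0), offset_s = 30)
    thr_prime <- lat$threshold_hz - lat$baseline_mean_hz
    analytic <- tau_on * log(gain / (gain - thr_prime))
    lat$onset_s - analytic
  }, numeric(1))
  expect_lt(abs(mean(err)), bin_s)
})

test_that("repeated-measures ANOVA reproduces a hand-computed oracle", {
  # 3 subjects x 2 phases x 2 conditions
  y <- c(5.1, 7.2, 4.4, 6.1, 6.0, 8.5,   # cond A: (s1,s2,s3) x (base, step)
         5.3, 6.0, 4.9, 5.4, 6.2, 7.1)   # cond B
  d <- data.frame(subject = rep(rep(c("s1", "s2", "s3"), 2), 2),
                  phase = rep(rep(c("base", "step"), each = 3), 2),
                  condition = rep(c("A", "B"), each = 6),
                  value = y)
  fit <- rm_anova(d)
  # independent sums-of-squares computation (textbook within-subject ANOVA)
  arr <- array(y, dim = c(3, 2, 2))  # subject x phase x condition
  gm <- mean(arr)
  m_s <- apply(arr, 1, mean); m_p <- apply(arr, 2, mean); m_c <- apply(arr, 3, mean)
  m_sp <- apply(arr, c(1, 2), mean); m_sc <- apply(arr, c(1, 3), mean)
  m_pc <- apply(arr, c(2, 3), mean)
  ss_p <- 3 * 2 * sum((m_p - gm)^2)
  ss_sp <- 2 * sum((m_sp - outer(m_s, rep(1, 2)) - outer(rep(1, 3), m_p) + gm)^2)
  ss_c <- 3 * 2 * sum((m_c - gm)^2)
  ss_sc <- 2 * sum((m_sc - outer(m_s, rep(1, 2)) - outer(rep(1, 3), m_c) + gm)^2)
  ss_pc <- 3 * sum((m_pc - outer(m_p, rep(1, 2)) - outer(rep(1, 2), m_c) + gm)^2)
  resid <- arr
  for (i in 1:3) for (j in 1:2) for (k in 1:2)
    resid[i, j, k] <- arr[i, j, k] - m_sp[i, j] - m_sc[i, k] - m_pc[j, k] +
      m_s[i] + m_p[j] + m_c[k] - gm
  ss_spc <- sum(resid^2)
  F_p <- (ss_p / 1) / (ss_sp / 2)
  F_c <- (ss_c / 1) / (ss_sc / 2)
  F_pc <- (ss_pc / 1) / (ss_spc / 2)
  expect_equal(fit$anova$F[fit$anova$effect == "phase"], F_p, tolerance = 1e-10)
  expect_equal(fit$anova$F[fit$anova$effect == "condition"], F_c, tolerance = 1e-10)
  expect_equal(fit$anova$F[fit$anova$effect == "phase:condition"], F_pc,
               tolerance = 1e-10)
  # adding a constant leaves every F unchanged
  d2 <- d; d2$value <- d2$value + 11
  expect_equal(rm_anova(d2)$anova$F, fit$anova$F, tolerance = 1e-8)
  # Bonferroni with a single comparison equals the raw p
  d1 <- d[d$condition == "A", ]
  fitA <- rm_anova(d1)
  expect_equal(fitA$posthoc$p_bonferroni, fitA$posthoc$p_raw)
  # incomplete designs are refused
  expect_error(rm_anova(d[-1, ]), "complete")
})

test_that("isoluminance scan returns the non-significant amplitude minimum", {
  mk <- function(setting, diff) data.frame(setting = setting, trial = 1:10,
                                           flash_hz = 5 + diff, bg_hz = 5)
  v <- rbind(mk("low", 2), mk("mid", 0), mk("high", -2))
  sc <- isoluminance_scan(v)
  expect_equal(sc$null_setting, "mid")
  expect_false(sc$excluded)
  allsig <- rbind(mk("low", 2), mk("mid", 1), mk("high", -2))
  expect_true(isoluminance_scan(allsig)$excluded)
})

test_that("isoluminance scan recovers the solver-exact null setting from spikes", {
  gains <- c(0.5, 1, 1.5)
  pops <- population_spec(3, class_fractions = c(mel_stepper = 0,
                                                 irradiance_tracker = 0,
                                                 rod_only = 1, null = 0),
                          prep = "cnga3_retina", seed = 8, param_jitter = 0.05)
  pop <- sample_population(pops)
  per_unit <- vector("list", 3); names(per_unit) <- names(pop)
  for (g in gains) {
    # the flicker flash is the rod-isoluminant 71% melanopsin step; the scan
    # perturbs the blue drive around the solved setting
    pair <- solve_silent_step(the_model, the_bg, target_contrast = 0.71,
                              blue_gain = g)
    fp <- build_flicker(pair, 100, 400, n_cycles = 150, nd = 3)
    ds <- simulate_dataset(fp, pops, the_model, dt = 0.005, population = pop)
    on <- epoch_onsets(fp, "flash")
    on <- on[on$t_on > 5, ]
    ar <- aligned_rates(ds, on$t_on, baseline_s = 0.1, response_s = 0.1)
    for (u in names(pop)) {
      d <- ar[ar$unit_id == u, ]
      per_unit[[u]] <- rbind(per_unit[[u]],
                             data.frame(setting = sprintf("%.2f", g),
                                        trial = d$trial, flash_hz = d$step_hz,
                                        bg_hz = d$baseline_hz))
    }
  }
  for (u in names(pop)) {
    sc <- isoluminance_scan(per_unit[[u]])
    expect_false(sc$excluded)
    expect_equal(sc$null_setting, "1.00")
  }
})

test_that("irradiance tracking requires a significantly positive rank correlation", {
  lf <- seq(10.5, 14.5, by = 0.5)
  up <- irradiance_tracking(2 + 1.5 * (lf - 10), lf)
  expect_true(up$tracker)
  expect_gt(up$slope, 0)
  flat <- irradiance_tracking(rep(3, length(lf)) + rep_len(c(0.01, -0.01), length(lf)), lf)
  expect_false(flat$tracker)
  down <- irradiance_tracking(20 - 1.5 * lf, lf)
  expect_false(down$tracker)
})

test_that("threshold irradiance reports the lowest significant level per arm", {
  set.seed(7)
  lev <- seq(10.1, 14.1, by = 0.5)
  mk <- function(arm, thr) do.call(rbind, lapply(sprintf("u%02d", 1:20), function(u)
    data.frame(unit_id = u, arm = arm, level_log = lev,
               baseline_hz = 5 + rnorm(length(lev), 0, 0.1),
               step_hz = 5 + ifelse(lev >= thr, 2, 0) + rnorm(length(lev), 0, 0.1))))
  th <- threshold_irradiance(rbind(mk("up", 12.1), mk("down", 13.1)))
  expect_equal(th$threshold_up, 12.1)
  expect_equal(th$threshold_down, 13.1)
  expect_equal(th$shift_log, 1.0)
  # nothing significant -> undefined thresholds
  null_tab <- do.call(rbind, lapply(sprintf("u%02d", 1:8), function(u)
    data.frame(unit_id = u, arm = "up", level_log = lev,
               baseline_hz = 5 + rnorm(length(lev), 0, 0.3),
               step_hz = 5 + rnorm(length(lev), 0, 0.3))))
  expect_true(is.na(threshold_irradiance(null_tab)$threshold_up))
})
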