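# Spike-train analysis: PSTHs, trial bin counts, responder classification,
# latencies, repeated-measures ANOVA, isoluminance scan, irradiance tracking
# and threshold irradiance.

count_between <- function(sp, a, b) {
  # sp sorted; counts spikes in [a, b)
  findInterval(b - 1e-12, sp) - findInterval(a - 1e-12, sp)
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate aligned to a set of events, with SEM across
#' trials and optional moving-average smoothing.
#'
#' @param spikes sorted spike times of one unit, s.
#' @param event_times event (trial) alignment times, s.
#' @param window `c(pre, post)` window relative to each event, s.
#' @param bin_s bin width, s.
#' @param smooth_bins odd number of bins for a centred moving average
#'   (1 = none).
#' @return An object of class `rate_estimate`: `centre` (bin centres, s
#'   relative to the event), `rate` (Hz), `sem`, `bin_s`, `n_trials`,
#'   `smoothing`.
#' @export
psth <- function(spikes, event_times, window = c(-30, 60), bin_s = 0.1,
                 smooth_bins = 1) {
  if (length(event_times) < 1L) stop("at least one event is required")
  nb <- round((window[2] - window[1]) / bin_s)
  breaks <- window[1] + (0:nb) * bin_s
  counts <- t(vapply(event_times, function(e) {
    rel <- spikes - e
    rel <- rel[rel >= window[1] & rel < window[2]]
    tabulate(pmin(nb, floor((rel - window[1]) / bin_s) + 1L), nbins = nb)
  }, integer(nb)))
  rate <- colMeans(counts) / bin_s
  sem <- apply(counts, 2, sd) / sqrt(nrow(counts)) / bin_s
  if (smooth_bins > 1) {
    rate <- moving_average(rate, smooth_bins)
    sem <- moving_average(sem, smooth_bins)
  }
  rate_estimate(breaks[-1] - bin_s / 2, rate, bin_s, sem = sem,
                n_trials = length(event_times),
                smoothing = if (smooth_bins > 1)
                  sprintf("%d-bin moving average", smooth_bins) else "none")
}

moving_average <- function(x, k) {
  # centred MA with edge replication
  half <- (k - 1) %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1):(half + length(x))]
}

#' Binned rate estimate
#'
#' @param centre bin centres, s.
#' @param rate firing rate per bin, Hz.
#' @param bin_s bin width, s.
#' @param sem optional SEM per bin.
#' @param n_trials number of trials averaged.
#' @param smoothing description of any smoothing applied.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(centre, rate, bin_s, sem = NULL, n_trials = 1,
                          smoothing = "none") {
  if (any(rate < 0)) stop("rates must be non-negative")
  structure(list(centre = centre, rate = rate, sem = sem, bin_s = bin_s,
                 n_trials = n_trials, smoothing = smoothing),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate: %d bins of %g s, %d trials, smoothing: %s>\n",
              length(x$centre), x$bin_s, x$n_trials, x$smoothing))
  invisible(x)
}

#' Trial bin count matrix
#'
#' Trials x time-bins matrix of firing rates (5 s bins by convention),
#' optionally normalised so the matrix maximum is exactly 1 (all-zero
#' matrices are returned unchanged with attribute `all_zero`).
#'
#' @inheritParams psth
#' @param normalise scale to the maximum firing rate over the epoch.
#' @return Matrix (trials x bins) of rates in Hz, or normalised rates.
#' @export
trial_bin_count <- function(spikes, event_times, window = c(-30, 60),
                            bin_s = 5, normalise = FALSE) {
  nb <- round((window[2] - window[1]) / bin_s)
  m <- t(vapply(event_times, function(e) {
    rel <- spikes - e
    rel <- rel[rel >= window[1] & rel < window[2]]
    tabulate(pmin(nb, floor((rel - window[1]) / bin_s) + 1L), nbins = nb)
  }, integer(nb))) / bin_s
  dimnames(m) <- list(trial = NULL,
                      centre = sprintf("%g", window[1] + (seq_len(nb) - 0.5) * bin_s))
  if (normalise) {
    mx <- max(m)
    if (mx > 0) m <- m / mx
    attr(m, "all_zero") <- mx == 0
  }
  m
}

#' Per-trial window rates aligned to events
#'
#' Mean firing rate in a baseline window before each event and a response
#' window after it, for every unit and trial.
#'
#' @param dataset a `spike_dataset`.
#' @param onsets event onset times, s (e.g. from [epoch_onsets()]).
#' @param baseline_s baseline window length before onset, s.
#' @param response_s response window length from onset, s.
#' @param units optional subset of unit ids.
#' @return Data frame: `unit_id`, `trial`, `baseline_hz`, `step_hz`.
#' @export
aligned_rates <- function(dataset, onsets, baseline_s = 30, response_s = 30,
                          units = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  ids <- units %||% names(dataset$spikes)
  out <- lapply(ids, function(u) {
    sp <- dataset$spikes[[u]]
    data.frame(unit_id = u, trial = seq_along(onsets),
               baseline_hz = vapply(onsets, function(t0)
                 count_between(sp, t0 - baseline_s, t0), numeric(1)) / baseline_s,
               step_hz = vapply(onsets, function(t0)
                 count_between(sp, t0, t0 + response_s), numeric(1)) / response_s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

paired_p <- function(base, step) {
  d <- step - base
  if (length(d) < 2L) stop("at least two trials are required")
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  t.test(step, base, paired = TRUE)$p.value
}

#' Classify light-responsive units
#'
#' Paired two-tailed t-test of baseline versus response-window firing rates
#' across trials; a unit is responsive when `p < alpha` and the rate change
#' lies in the tested direction. Zero-variance, zero-mean differences are not
#' responsive (p = 1 by convention).
#'
#' @param rates an [aligned_rates()] data frame.
#' @param alpha significance level (0.05).
#' @param direction `"increase"`, `"decrease"` or `"either"`.
#' @return Data frame: `unit_id`, `p_value`, `delta_hz`, `responsive`.
#' @export
classify_responsive <- function(rates, alpha = 0.05,
                                direction = c("increase", "decrease", "either")) {
  direction <- match.arg(direction)
  res <- lapply(split(rates, rates$unit_id), function(d) {
    p <- paired_p(d$baseline_hz, d$step_hz)
    delta <- mean(d$step_hz) - mean(d$baseline_hz)
    ok <- switch(direction, increase = delta > 0, decrease = delta < 0, either = TRUE)
    data.frame(unit_id = d$unit_id[1], p_value = p, delta_hz = delta,
               responsive = p < alpha && ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$unit_id), , drop = FALSE]
}

#' Change in firing rate
#'
#' Mean response-window rate minus mean baseline rate, per unit (baseline
#' 30 s before steps on steady backgrounds, 10 s on the ramp protocol).
#'
#' @param rates an [aligned_rates()] data frame.
#' @return Data frame: `unit_id`, `delta_hz`.
#' @export
delta_firing_rate <- function(rates) {
  out <- do.call(rbind, lapply(split(rates, rates$unit_id), function(d)
    data.frame(unit_id = d$unit_id[1],
               delta_hz = mean(d$step_hz) - mean(d$baseline_hz),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$unit_id), , drop = FALSE]
}

#' Response onset and offset latencies (1-SD rule)
#'
#' The threshold line is the mean plus one standard deviation of the
#' baseline-window bins of the rate estimate. Onset latency is the time after
#' stimulus onset at which the rate crosses above the line; offset latency is
#' the time after stimulus offset at which the rate returns below it. On a
#' finite-trial PSTH roughly one baseline bin in six exceeds the 1-SD line by
#' chance, so a crossing only counts when it is sustained for `sustain_s`
#' seconds of consecutive bins; on noiseless rates this is identical to the
#' first crossing. Latencies that never occur are `NA`, never fabricated. A
#' zero baseline SD sets the line at the baseline mean and flags the estimate
#' as degenerate.
#'
#' @param rate a [rate_estimate()] (time axis relative to stimulus onset).
#' @param baseline_window `c(from, to)` of the baseline, s relative to onset.
#' @param onset_s,offset_s stimulus onset and offset times on the estimate's
#'   time axis, s.
#' @param sustain_s minimum time the rate must stay across the line for a
#'   crossing to count, s.
#' @return List: `onset_s`, `offset_s` (s after onset/offset, `NA` if no
#'   crossing), `threshold_hz`, `baseline_mean_hz`, `degenerate`.
#' @export
response_latencies <- function(rate, baseline_window = c(-30, 0),
                               onset_s = 0, offset_s = 30, sustain_s = 1) {
  stopifnot(inherits(rate, "rate_estimate"))
  bl <- rate$rate[rate$centre >= baseline_window[1] & rate$centre < baseline_window[2]]
  if (length(bl) < 2L) stop("baseline window must contain at least two bins")
  degenerate <- sd(bl) == 0
  thr <- mean(bl) + sd(bl)
  k <- max(1L, ceiling(sustain_s / rate$bin_s))
  first_sustained <- function(hit) {
    # index of the first TRUE that starts a run of >= k TRUEs (a shorter
    # terminal run also counts: the trace simply ended while across the line)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & (r$lengths >= k | ends == length(hit))
    if (any(ok)) starts[which(ok)[1]] else NA_integer_
  }
  sel_on <- rate$centre > onset_s
  i_on <- first_sustained(rate$rate[sel_on] > thr)
  onset <- if (!is.na(i_on)) rate$centre[sel_on][i_on] - onset_s else NA_real_
  sel_off <- rate$centre > offset_s
  i_off <- first_sustained(rate$rate[sel_off] < thr)
  offset <- if (!is.na(i_off)) rate$centre[sel_off][i_off] - offset_s else NA_real_
  list(onset_s = onset, offset_s = offset, threshold_hz = thr,
       baseline_mean_hz = mean(bl), degenerate = degenerate)
}

#' Two-way repeated-measures ANOVA with Bonferroni post-hocs
#'
#' Within-subject decomposition of firing rates over `phase` (baseline versus
#' step) and a second within-subject factor (`condition`: contrast, ND level
#' or drug state), with subjects as the blocking factor
#' (`aov(value ~ phase * condition + Error(subject/(phase * condition)))`).
#' Pairwise baseline-versus-step comparisons within each condition are
#' Bonferroni-adjusted (p multiplied by the number of comparisons, capped at
#' 1).
#'
#' @param data data frame with columns `subject`, `phase`, `condition`,
#'   `value`; the table must be complete and balanced (no imputation).
#' @return List with `anova` (data frame: effect, df1, df2, F, p) and
#'   `posthoc` (per condition: mean difference, t, raw and adjusted p).
#' @export
rm_anova <- function(data) {
  need <- c("subject", "phase", "condition", "value")
  if (!all(need %in% names(data))) stop("data must have columns ", paste(need, collapse = ", "))
  data$subject <- factor(data$subject)
  data$phase <- factor(data$phase)
  data$condition <- factor(data$condition)
  tab <- table(data$subject, data$phase, data$condition)
  if (any(tab != 1))
    stop("design must be complete and balanced: one observation per subject x phase x condition")
  one_cond <- nlevels(data$condition) < 2L
  fit <- if (one_cond)
    aov(value ~ phase + Error(subject / phase), data = data)
  else
    aov(value ~ phase * condition + Error(subject / (phase * condition)),
        data = data)
  sm <- summary(fit)
  eff <- if (one_cond) "phase" else c("phase", "condition", "phase:condition")
  rows <- lapply(eff, function(e) {
    for (stratum in sm) {
      t1 <- stratum[[1]]
      hit <- trimws(rownames(t1)) == e
      if (any(hit)) {
        i <- which(hit)
        resid <- which(trimws(rownames(t1)) == "Residuals")
        return(data.frame(effect = e, df1 = t1$Df[i], df2 = t1$Df[resid],
                          F = t1$`F value`[i], p = t1$`Pr(>F)`[i],
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  anova_tab <- do.call(rbind, rows)
  rownames(anova_tab) <- NULL
  conds <- levels(data$condition)
  phases <- levels(data$phase)
  if (length(phases) != 2L) stop("posthoc comparisons expect exactly two phases")
  ph <- lapply(conds, function(cc) {
    d <- data[data$condition == cc, ]
    d <- d[order(d$subject, d$phase), ]
    a <- d$value[d$phase == phases[1]]
    b <- d$value[d$phase == phases[2]]
    tt <- t.test(b, a, paired = TRUE)
    data.frame(condition = cc, mean_diff = mean(b - a),
               t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  posthoc <- do.call(rbind, ph)
  posthoc$p_bonferroni <- pmin(1, posthoc$p_raw * nrow(posthoc))
  list(anova = anova_tab, posthoc = posthoc)
}

#' Isoluminance scan over blue-gain settings
#'
#' Per-setting flicker response amplitude (flash-window minus
#' background-window rate, paired over cycles). The null setting is the
#' amplitude minimum provided it is non-significant against baseline; a unit
#' significant at every setting is excluded (the online-calibration exclusion
#' rule).
#'
#' @param responses data frame with columns `setting`, `trial`, `flash_hz`,
#'   `bg_hz` for one unit.
#' @param alpha significance level.
#' @return List: `table` (per setting: amplitude, p), `null_setting` (`NA` if
#'   excluded), `excluded`.
#' @export
isoluminance_scan <- function(responses, alpha = 0.05) {
  need <- c("setting", "trial", "flash_hz", "bg_hz")
  if (!all(need %in% names(responses)))
    stop("responses must have columns ", paste(need, collapse = ", "))
  tab <- do.call(rbind, lapply(split(responses, responses$setting), function(d)
    data.frame(setting = d$setting[1],
               amplitude_hz = mean(d$flash_hz - d$bg_hz),
               p_value = paired_p(d$bg_hz, d$flash_hz),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  excluded <- all(tab$p_value < alpha)
  null_setting <- if (excluded) NA else {
    cand <- tab[which.min(abs(tab$amplitude_hz)), ]
    if (cand$p_value >= alpha) cand$setting else NA
  }
  if (!excluded && is.na(null_setting)) excluded <- TRUE
  list(table = tab, null_setting = null_setting, excluded = excluded)
}

#' Irradiance-tracking classification
#'
#' A unit tracks irradiance when the rank correlation between its mean rate
#' per ramp segment and the log background flux is significantly positive.
#'
#' @param rate_hz mean firing rate per ramp segment, Hz.
#' @param log_flux log10 background flux per segment.
#' @param alpha significance level.
#' @return List: `tracker`, `rho`, `p_value`, `slope` (Hz per log unit, least
#'   squares).
#' @export
irradiance_tracking <- function(rate_hz, log_flux, alpha = 0.05) {
  stopifnot(length(rate_hz) == length(log_flux), length(rate_hz) >= 4)
  ct <- suppressWarnings(cor.test(rate_hz, log_flux, method = "spearman",
                                  exact = FALSE))
  slope <- unname(coef(lm(rate_hz ~ log_flux))[2])
  list(tracker = ct$p.value < alpha && unname(ct$estimate) > 0,
       rho = unname(ct$estimate), p_value = ct$p.value, slope = slope)
}

#' Threshold irradiance per ramp arm
#'
#' Classifies responsiveness (paired t across units, increase direction,
#' Bonferroni-corrected across the levels within each arm) at every
#' background level of the irradiance-ramp protocol, and reports the lowest
#' significant background per arm plus the light-adaptation shift
#' (down-arm threshold minus up-arm threshold, log units).
#'
#' @param step_table data frame with columns `unit_id`, `arm` (`"up"` /
#'   `"down"`), `level_log` (log10 background flux), `baseline_hz`, `step_hz`
#'   (per-unit means at that level).
#' @param alpha familywise significance level.
#' @return List: `table` (per arm x level: delta, raw and adjusted p,
#'   significance), `threshold_up`, `threshold_down` (log10 flux; `NA` when
#'   no level is significant), `shift_log`.
#' @export
threshold_irradiance <- function(step_table, alpha = 0.05) {
  need <- c("unit_id", "arm", "level_log", "baseline_hz", "step_hz")
  if (!all(need %in% names(step_table)))
    stop("step_table must have columns ", paste(need, collapse = ", "))
  res <- list()
  for (arm in unique(step_table$arm)) {
    d_arm <- step_table[step_table$arm == arm, ]
    levels <- sort(unique(d_arm$level_log))
    k <- length(levels)
    for (L in levels) {
      d <- d_arm[abs(d_arm$level_log - L) < 1e-9, ]
      p <- paired_p(d$baseline_hz, d$step_hz)
      delta <- mean(d$step_hz - d$baseline_hz)
      res[[length(res) + 1]] <- data.frame(
        arm = arm, level_log = L, n_units = nrow(d), delta_hz = delta,
        p_raw = p, p_bonferroni = min(1, p * k), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, res)
  tab$significant <- tab$p_bonferroni < alpha & tab$delta_hz > 0
  thr <- function(arm) {
    sig <- tab$level_log[tab$arm == arm & tab$significant]
    if (length(sig)) min(sig) else NA_real_
  }
  up <- thr("up"); down <- thr("down")
  list(table = tab, threshold_up = up, threshold_down = down,
       shift_log = down - up)
}

#' Log background melanopsin flux at each ramp step
#'
#' Helper for the ramp protocol: per step epoch, the log10
#' melanopsin-effective flux of the background at that epoch's ND level.
#'
#' @param protocol a ramp `protocol` (from [build_protocol2()]).
#' @param model the [silencing_model()].
#' @param background the background [stimulus_setting()] (ND ignored; the
#'   epoch ND is used).
#' @return Data frame: `t_on`, `duration`, `arm`, `nd`, `level_log`.
#' @export
ramp_step_levels <- function(protocol, model, background) {
  on <- epoch_onsets(protocol, kind = "step")
  base <- setting_flux(model, with_nd(background, 0), "melanopsin")$flux
  on$level_log <- log10(base * 10^(-on$nd))
  on
}

#' Per-unit step table for the ramp protocol
#'
#' Builds the input of [threshold_irradiance()] from a simulated (or loaded)
#' dataset of the irradiance-ramp protocol: per unit, arm and ND level, the
#' mean baseline (10 s before the step) and step-window rates across repeats.
#'
#' @param dataset a `spike_dataset` over a [build_protocol2()] protocol.
#' @param model the [silencing_model()].
#' @param background the shared background setting.
#' @param baseline_s baseline window, s (10 s on the ramp protocol).
#' @return Data frame suitable for [threshold_irradiance()].
#' @export
protocol2_step_table <- function(dataset, model, background, baseline_s = 10) {
  lev <- ramp_step_levels(dataset$protocol, model, background)
  out <- list()
  for (u in names(dataset$spikes)) {
    sp <- dataset$spikes[[u]]
    base <- vapply(lev$t_on, function(t0)
      count_between(sp, t0 - baseline_s, t0), numeric(1)) / baseline_s
    step <- vapply(seq_len(nrow(lev)), function(i)
      count_between(sp, lev$t_on[i], lev$t_on[i] + lev$duration[i]),
      numeric(1)) / lev$duration
    d <- data.frame(unit_id = u, arm = lev$arm, level_log = lev$level_log,
                    baseline_hz = base, step_hz = step, stringsAsFactors = FALSE)
    agg <- aggregate(cbind(baseline_hz, step_hz) ~ unit_id + arm + level_log,
                     data = d, FUN = mean)
    out[[u]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-unit segment rates on the ramp protocol
#'
#' Mean rate during every hold epoch (steady background at each ND level),
#' paired with the log background melanopsin flux, for irradiance-tracking
#' classification.
#'
#' @inheritParams protocol2_step_table
#' @return Data frame: `unit_id`, `arm`, `level_log`, `rate_hz`.
#' @export
protocol2_segment_rates <- function(dataset, model, background) {
  hold <- epoch_onsets(dataset$protocol, kind = "hold")
  base <- setting_flux(model, with_nd(background, 0), "melanopsin")$flux
  hold$level_log <- log10(base * 10^(-hold$nd))
  out <- list()
  for (u in names(dataset$spikes)) {
    sp <- dataset$spikes[[u]]
    r <- vapply(seq_len(nrow(hold)), function(i)
      count_between(sp, hold$t_on[i], hold$t_on[i] + hold$duration[i]),
      numeric(1)) / hold$duration
    out[[u]] <- data.frame(unit_id = u, arm = hold$arm,
                           level_log = hold$level_log, rate_hz = r,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end unit classification
#'
#' Combines the contrast-step analysis (protocol 1) with the optional
#' irradiance-ramp analysis (protocol 2): a unit is a `stepper` when its
#' pooled baseline-versus-step comparison is significant (increase), else a
#' `tracker` when its hold-segment rates track log background flux, else
#' `none`. Step-responsive units also receive 1-SD onset/offset latencies
#' estimated from the PSTH at the highest presented contrast.
#'
#' @param dataset_steps `spike_dataset` over a [build_protocol1()] protocol.
#' @param dataset_ramp optional `spike_dataset` over a [build_protocol2()]
#'   protocol for the same units.
#' @param model the [silencing_model()] (required with `dataset_ramp`).
#' @param background the shared background setting (required with
#'   `dataset_ramp`).
#' @param alpha significance level.
#' @param baseline_s baseline window for the step comparison, s.
#' @param latency_bin_s,latency_smooth_bins PSTH resolution for the latency
#'   estimate. The default (0.5 s bins, 3-bin moving average) keeps the 1-SD
#'   line well below the expected 1-2 Hz response amplitude at ~14 trials; finer
#'   grids are appropriate for larger trial counts (see the methods
#'   vignette).
#' @return Data frame (one row per unit): `unit_id`, `class`, `p_step`,
#'   `delta_hz`, `onset_s`, `offset_s`, `tracker_rho`, `tracker_p`,
#'   `excluded`, `reason`.
#' @export
classify_units <- function(dataset_steps, dataset_ramp = NULL, model = NULL,
                           background = NULL, alpha = 0.05, baseline_s = 30,
                           latency_bin_s = 0.5, latency_smooth_bins = 3) {
  on <- epoch_onsets(dataset_steps$protocol, kind = "step")
  step_s <- on$duration[1]
  rates <- aligned_rates(dataset_steps, on$t_on, baseline_s = baseline_s,
                         response_s = step_s)
  cls <- classify_responsive(rates, alpha = alpha, direction = "increase")
  labs <- on$label
  top <- labs[which.max(suppressWarnings(as.numeric(sub("^c", "", labs))))]
  top_on <- on$t_on[on$label == top]
  track <- NULL
  if (!is.null(dataset_ramp)) {
    if (is.null(model) || is.null(background))
      stop("model and background are required for the ramp analysis")
    seg <- protocol2_segment_rates(dataset_ramp, model, background)
    track <- lapply(split(seg, seg$unit_id), function(d)
      irradiance_tracking(d$rate_hz, d$level_log, alpha = alpha))
  }
  out <- lapply(seq_len(nrow(cls)), function(i) {
    u <- cls$unit_id[i]
    onset <- offset <- NA_real_
    if (cls$responsive[i]) {
      pe <- psth(dataset_steps$spikes[[u]], top_on,
                 window = c(-baseline_s, step_s + 60), bin_s = latency_bin_s,
                 smooth_bins = latency_smooth_bins)
      lat <- response_latencies(pe, baseline_window = c(-baseline_s, 0),
                                onset_s = 0, offset_s = step_s)
      onset <- lat$onset_s; offset <- lat$offset_s
    }
    tr <- if (!is.null(track)) track[[u]] else NULL
    class <- if (cls$responsive[i]) "stepper"
             else if (!is.null(tr) && tr$tracker) "tracker"
             else "none"
    data.frame(unit_id = u, class = class, p_step = cls$p_value[i],
               delta_hz = cls$delta_hz[i], onset_s = onset, offset_s = offset,
               tracker_rho = if (is.null(tr)) NA_real_ else tr$rho,
               tracker_p = if (is.null(tr)) NA_real_ else tr$p_value,
               excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
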