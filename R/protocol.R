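# Stimulation protocols as timestamped epoch tables, and their rendering to
# continuous per-pigment irradiance traces.

new_epoch <- function(kind, duration, setting, setting_end = NULL,
                      label = "", arm = NA_character_) {
  if (is.null(setting_end)) setting_end <- setting
  data.frame(kind = kind, t_start = NA_real_, duration = duration,
             blue_start = setting$blue, yellow_start = setting$yellow,
             nd_start = setting$nd,
             blue_end = setting_end$blue, yellow_end = setting_end$yellow,
             nd_end = setting_end$nd,
             arm = arm, label = label, stringsAsFactors = FALSE)
}

assemble_protocol <- function(epochs, seed = NA_integer_, metadata = list()) {
  ep <- do.call(rbind, epochs)
  if (nrow(ep) == 0L) stop("a protocol needs at least one epoch")
  if (any(ep$duration <= 0)) stop("epoch durations must be positive")
  ep$t_start <- cumsum(c(0, head(ep$duration, -1)))
  rownames(ep) <- NULL
  structure(list(epochs = ep, seed = seed, metadata = metadata),
            class = "protocol")
}

#' Total protocol duration
#' @param protocol a `protocol` object.
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "protocol"))
  sum(protocol$epochs$duration)
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol%s: %d epochs, %.1f min>\n",
              if (!is.null(x$metadata$id)) paste0(" ", x$metadata$id) else "",
              nrow(x$epochs), protocol_duration(x) / 60))
  print(table(x$epochs$kind))
  invisible(x)
}

setting_of <- function(epoch_row, which = c("start", "end")) {
  which <- match.arg(which)
  stimulus_setting(blue = epoch_row[[paste0("blue_", which)]],
                   yellow = epoch_row[[paste0("yellow_", which)]],
                   nd = epoch_row[[paste0("nd_", which)]])
}

with_nd <- function(setting, nd) stimulus_setting(setting$blue, setting$yellow, nd)

#' Steady-background contrast-step protocol (protocol 1)
#'
#' After an initial adaptation period on the shared background, melanopsin
#' steps at the supplied contrasts are interleaved pseudo-randomly (seeded
#' Fisher-Yates shuffle of the repeats-by-contrasts block list), each step
#' followed by an inter-stimulus interval on the background. Defaults follow
#' the dLGN configuration: 30 s steps, 210 s ISI, at least 14 repeats, 10 min
#' adaptation; the retinal variant used 20 s steps and 180 s ISI.
#'
#' @param pairs list of [solve_silent_step()] pairs sharing one background.
#' @param step_s step duration, s.
#' @param isi_s inter-stimulus interval, s.
#' @param repeats presentations per pair.
#' @param adaptation_s initial adaptation duration, s.
#' @param seed integer seed for the pseudo-random interleaving.
#' @param id,preparation metadata strings.
#' @return A `protocol` object.
#' @export
build_protocol1 <- function(pairs, step_s = 30, isi_s = 210, repeats = 14,
                            adaptation_s = 600, seed = 1,
                            id = "protocol1", preparation = "dLGN") {
  if (length(pairs) == 0L) stop("pairs must contain at least one stimulus pair")
  stopifnot(repeats >= 1, step_s > 0, isi_s > 0)
  bg <- pairs[[1]]$background
  for (p in pairs)
    if (abs(p$background$blue - bg$blue) + abs(p$background$yellow - bg$yellow) +
        abs(p$background$nd - bg$nd) > 1e-12)
      stop("all pairs must share the same background setting")
  order <- with_seed(seed, sample(rep(seq_along(pairs), repeats)))
  eps <- list(new_epoch("adaptation", adaptation_s, bg, label = "adaptation"))
  for (k in order) {
    pr <- pairs[[k]]
    lab <- sprintf("c%02d", round(100 * pr$target_contrast))
    eps <- c(eps, list(new_epoch("step", step_s, pr$step, label = lab),
                       new_epoch("background", isi_s, bg, label = "isi")))
  }
  assemble_protocol(eps, seed = seed,
                    metadata = list(id = id, preparation = preparation,
                                    contrasts = vapply(pairs, `[[`, numeric(1),
                                                       "target_contrast")))
}

#' Neutral-density irradiance-ramp protocol (protocol 2)
#'
#' Background irradiance ramps slowly across a range of neutral-density
#' settings (0.5 ND per 200 s), holding 10 s at each half-log level before a
#' 30 s melanopsin-isolating step, so each 0.5 ND cycle lasts 4 minutes. The
#' first level of each arm substitutes a steady background for the ramp slot,
#' so that 9 levels per direction give 18 equal cycles (72 minutes for a ramp
#' up and down), flanked by 4 minute adaptation epochs.
#'
#' @param pair the [solve_silent_step()] pair (weights fixed; the ND wedge
#'   supplies the irradiance modulation).
#' @param start_nd starting neutral density (4 ramps up first, 0 ramps down
#'   first).
#' @param end_nd density at the turn-around point.
#' @param nd_step density increment per cycle.
#' @param ramp_s,hold_s,step_s durations of the ramp, hold and step slots, s.
#' @param adaptation_s adaptation duration at either end, s.
#' @param id,preparation metadata strings.
#' @return A `protocol` object; ramp epochs interpolate ND linearly in
#'   density.
#' @export
build_protocol2 <- function(pair, start_nd = 4, end_nd = 0, nd_step = 0.5,
                            ramp_s = 200, hold_s = 10, step_s = 30,
                            adaptation_s = 240, id = "protocol2",
                            preparation = "dLGN") {
  span <- abs(start_nd - end_nd)
  if (abs(span / nd_step - round(span / nd_step)) > 1e-9)
    stop("ND range must be divisible by nd_step")
  bg <- pair$background
  step <- pair$step
  arm_levels <- function(from, to) seq(from, to, by = if (to > from) nd_step else -nd_step)
  arm_name <- function(levels) if (levels[length(levels)] < levels[1] || all(diff(levels) == 0))
    "up" else "down"  # decreasing ND = increasing irradiance
  eps <- list(new_epoch("adaptation", adaptation_s, with_nd(bg, start_nd),
                        label = "adaptation"))
  arms <- list(arm_levels(start_nd, end_nd), arm_levels(end_nd, start_nd))
  for (levels in arms) {
    arm <- if (levels[1] > levels[length(levels)]) "up" else "down"
    prev <- levels[1]
    for (i in seq_along(levels)) {
      nd <- levels[i]
      lab <- sprintf("ND%.1f", nd)
      if (i == 1L)
        eps <- c(eps, list(new_epoch("background", ramp_s, with_nd(bg, nd),
                                     label = lab, arm = arm)))
      else
        eps <- c(eps, list(new_epoch("ramp", ramp_s, with_nd(bg, prev),
                                     with_nd(bg, nd), label = lab, arm = arm)))
      eps <- c(eps, list(new_epoch("hold", hold_s, with_nd(bg, nd),
                                   label = lab, arm = arm),
                         new_epoch("step", step_s, with_nd(step, nd),
                                   label = lab, arm = arm)))
      prev <- nd
    }
  }
  eps <- c(eps, list(new_epoch("adaptation", adaptation_s, with_nd(bg, start_nd),
                               label = "adaptation")))
  assemble_protocol(eps, metadata = list(id = id, preparation = preparation,
                                         start_nd = start_nd, end_nd = end_nd,
                                         nd_step = nd_step,
                                         contrast = pair$target_contrast))
}

#' Calibration flicker protocol
#'
#' Alternating presentations of the yellow background and a brief blue flash
#' (e.g. 50 ms blue : 200 ms yellow for 4 Hz, 100 : 400 for 2 Hz), used for
#' the online identification of the rod-isoluminant blue setting at a
#' moderate background (ND 3).
#'
#' @param pair a [solve_silent_step()] pair (flash = step setting).
#' @param blue_ms,yellow_ms flash and background durations, ms.
#' @param n_cycles number of background + flash cycles.
#' @param nd neutral density applied to both members.
#' @param id,preparation metadata strings.
#' @return A `protocol`; each cycle contributes a background then a flash
#'   epoch, and `metadata$flicker_hz` records `1000 / (blue_ms + yellow_ms)`.
#' @export
build_flicker <- function(pair, blue_ms = 50, yellow_ms = 200, n_cycles = 40,
                          nd = 3, id = "flicker", preparation = "dLGN") {
  stopifnot(blue_ms > 0, yellow_ms > 0, n_cycles >= 1)
  bg <- with_nd(pair$background, nd)
  fl <- with_nd(pair$step, nd)
  eps <- list()
  for (i in seq_len(n_cycles))
    eps <- c(eps, list(new_epoch("background", yellow_ms / 1000, bg, label = "bg"),
                       new_epoch("flash", blue_ms / 1000, fl, label = "flash")))
  assemble_protocol(eps, metadata = list(id = id, preparation = preparation,
                                         flicker_hz = 1000 / (blue_ms + yellow_ms)))
}

#' Dark-adapted blue pulse protocol
#'
#' Blue pulses over a range of melanopsin-effective irradiances from
#' darkness, separated by seeded uniform dark intervals (50-110 s by
#' default).
#'
#' @param model a [silencing_model()] used to scale the blue primary to each
#'   requested irradiance.
#' @param irradiances_log log10 melanopsin-effective photons cm^-2 s^-1 of the
#'   pulses (reference range 11.21-15.1).
#' @param pulse_s pulse duration, s.
#' @param isi_range_s dark inter-stimulus-interval bounds, s.
#' @param seed seed for the ISI draws.
#' @param id,preparation metadata strings.
#' @return A `protocol` alternating dark and pulse epochs.
#' @export
build_dark_pulses <- function(model, irradiances_log, pulse_s = 10,
                              isi_range_s = c(50, 110), seed = 1,
                              id = "dark_pulses", preparation = "dLGN") {
  stopifnot(length(irradiances_log) >= 1, isi_range_s[1] <= isi_range_s[2])
  dark <- stimulus_setting(0, 0, 0)
  isis <- with_seed(seed, runif(length(irradiances_log), isi_range_s[1], isi_range_s[2]))
  eps <- list()
  for (i in seq_along(irradiances_log)) {
    L <- irradiances_log[i]
    w <- 10^L / model$M["melanopsin", "blue"]
    if (w > model$max_drive)
      stop(sprintf("pulse at %.2f log needs blue drive %.3g > max_drive %g",
                   L, w, model$max_drive))
    eps <- c(eps, list(new_epoch("dark", isis[i], dark, label = "dark"),
                       new_epoch("flash", pulse_s, stimulus_setting(blue = w),
                                 label = sprintf("log%.2f", L))))
  }
  assemble_protocol(eps, seed = seed,
                    metadata = list(id = id, preparation = preparation,
                                    irradiances_log = irradiances_log))
}

#' Rod-favouring flash protocol
#'
#' Brief yellow flashes from darkness (50 ms, attenuated to ND 3, at 1 Hz):
#' the basic rod-response characterisation stimulus.
#'
#' @param yellow_setting the yellow drive used for the flash (unit drive by
#'   default); `nd` is applied on top.
#' @param flash_ms flash duration, ms.
#' @param rate_hz flash rate, Hz.
#' @param n number of flashes.
#' @param nd neutral density of the flash.
#' @param id,preparation metadata strings.
#' @return A `protocol` of `n` flash epochs separated by darkness, total
#'   duration `n / rate_hz` seconds.
#' @export
build_rod_flash <- function(yellow_setting = stimulus_setting(yellow = 1),
                            flash_ms = 50, rate_hz = 1, n = 10, nd = 3,
                            id = "rod_flash", preparation = "dLGN") {
  stopifnot(flash_ms > 0, rate_hz > 0, n >= 1, flash_ms / 1000 < 1 / rate_hz)
  dark <- stimulus_setting(0, 0, 0)
  fl <- with_nd(yellow_setting, yellow_setting$nd + nd)
  gap <- 1 / rate_hz - flash_ms / 1000
  eps <- list()
  for (i in seq_len(n))
    eps <- c(eps, list(new_epoch("flash", flash_ms / 1000, fl, label = "flash"),
                       new_epoch("dark", gap, dark, label = "dark")))
  assemble_protocol(eps, metadata = list(id = id, preparation = preparation,
                                         rate_hz = rate_hz))
}

#' Concatenate repeats of a protocol
#'
#' @param protocol a `protocol`.
#' @param times number of back-to-back repeats.
#' @return A `protocol` with the epoch table tiled `times` times.
#' @export
repeat_protocol <- function(protocol, times) {
  stopifnot(inherits(protocol, "protocol"), times >= 1)
  ep <- protocol$epochs[rep(seq_len(nrow(protocol$epochs)), times), ]
  assemble_protocol(split(ep, seq_len(nrow(ep))), seed = protocol$seed,
                    metadata = c(protocol$metadata, list(repeats = times)))
}

#' Render a protocol to per-pigment irradiance traces
#'
#' Samples the protocol on a uniform time grid (piecewise-constant over each
#' `dt` bin, evaluated at the bin start). Drive weights interpolate linearly
#' across ramp epochs and ND interpolates linearly in density, i.e.
#' log-linearly in flux.
#'
#' @param protocol a `protocol`.
#' @param model a [silencing_model()] supplying the unit-flux matrix.
#' @param dt sample interval, s.
#' @param pigments pigment names to render.
#' @return An object of class `stimulus_trace`: `time` (s), `dt`, `flux`
#'   (matrix, one column per pigment, photons cm^-2 s^-1), `nd`, `epoch`
#'   (epoch index per sample) and the protocol's epoch table.
#' @export
render_trace <- function(protocol, model, dt = 0.1,
                         pigments = c("rod", "melanopsin")) {
  stopifnot(inherits(protocol, "protocol"), inherits(model, "silencing_model"))
  ep <- protocol$epochs
  total <- sum(ep$duration)
  n <- round(total / dt)
  t <- (seq_len(n) - 1) * dt
  idx <- findInterval(t + 1e-9, c(0, cumsum(ep$duration)))
  idx[idx > nrow(ep)] <- nrow(ep)
  frac <- (t - ep$t_start[idx]) / ep$duration[idx]
  blue <- ep$blue_start[idx] + frac * (ep$blue_end[idx] - ep$blue_start[idx])
  yellow <- ep$yellow_start[idx] + frac * (ep$yellow_end[idx] - ep$yellow_start[idx])
  nd <- ep$nd_start[idx] + frac * (ep$nd_end[idx] - ep$nd_start[idx])
  att <- 10^(-nd)
  flux <- vapply(pigments, function(p)
    (blue * model$M[p, "blue"] + yellow * model$M[p, "yellow"]) * att,
    numeric(n))
  structure(list(time = t, dt = dt, flux = flux, nd = nd, epoch = idx,
                 epochs = ep),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace: %d samples, dt %g s, pigments: %s>\n",
              length(x$time), x$dt, paste(colnames(x$flux), collapse = ", ")))
  invisible(x)
}

#' Onset times of protocol epochs
#'
#' @param protocol a `protocol`.
#' @param kind epoch kind to select (e.g. `"step"`, `"flash"`).
#' @param label optional label filter.
#' @return Data frame with `t_on`, `duration`, `label`, `arm`, `nd`.
#' @export
epoch_onsets <- function(protocol, kind = "step", label = NULL) {
  ep <- protocol$epochs
  sel <- ep$kind %in% kind
  if (!is.null(label)) sel <- sel & ep$label %in% label
  data.frame(t_on = ep$t_start[sel], duration = ep$duration[sel],
             label = ep$label[sel], arm = ep$arm[sel], nd = ep$nd_start[sel],
             stringsAsFactors = FALSE)
}
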