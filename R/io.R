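# File formats, fixtures and the reproducible end-to-end run.

#' Read a spectral function from a two-column CSV
#'
#' Expects a header row and two columns (wavelength in nm, value), validates
#' monotonicity and sign (errors name the offending row), and regrids to the
#' configured wavelength grid by linear interpolation (zero outside the
#' measured range). Total photon counts are preserved to within 0.1% for
#' smooth spectra.
#'
#' @param path CSV file path.
#' @param grid target wavelength grid, nm.
#' @param kind spectral kind of the file contents.
#' @return A [spectral_function()].
#' @export
read_spd <- function(path, grid = default_grid(),
                     kind = c("power_density", "sensitivity", "transmission")) {
  kind <- match.arg(kind)
  d <- read.csv(path)
  if (ncol(d) < 2L) stop("expected a two-column CSV with a header row")
  w <- d[[1]]; v <- d[[2]]
  bad <- which(!is.finite(w) | !is.finite(v))
  if (length(bad)) stop("non-numeric or missing entry at row ", bad[1])
  nm <- which(diff(w) <= 0)
  if (length(nm)) stop("wavelengths not strictly increasing at row ", nm[1] + 1)
  neg <- which(v < 0)
  if (length(neg)) stop("negative value at row ", neg[1])
  vi <- approx(w, v, xout = grid, rule = 1)$y
  vi[is.na(vi)] <- 0
  spectral_function(grid, vi, kind)
}

#' Write a spectral function to CSV
#'
#' @param sf a [spectral_function()].
#' @param path output CSV path.
#' @export
write_spd <- function(sf, path) {
  stopifnot(inherits(sf, "spectral_function"))
  write.csv(data.frame(wavelength_nm = sf$wavelength, value = sf$value),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialise a protocol to JSON
#'
#' Epochs with kinds, start times (s from 0), durations, inline settings and
#' labels; lossless round trip with [read_protocol_json()].
#'
#' @param protocol a `protocol`.
#' @param path output path.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol"))
  jsonlite::write_json(list(epochs = protocol$epochs, seed = protocol$seed,
                            metadata = protocol$metadata),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_protocol_json
#' @return `read_protocol_json` returns the `protocol` object.
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- as.data.frame(x$epochs, stringsAsFactors = FALSE)
  if (is.null(ep$arm)) ep$arm <- NA_character_
  ep$arm <- as.character(ep$arm)
  structure(list(epochs = ep,
                 seed = x$seed %||% NA_integer_,
                 metadata = x$metadata %||% list()),
            class = "protocol")
}

#' Write spike times to long-format CSV
#'
#' Columns `unit_id`, `trial_id`, `spike_time_s`; continuous-protocol
#' datasets use trial 0 throughout (trials are defined by alignment to
#' protocol events at analysis time).
#'
#' @param dataset a `spike_dataset`.
#' @param path output CSV path.
#' @export
write_spikes_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  n <- vapply(dataset$spikes, length, integer(1))
  d <- data.frame(unit_id = rep(names(dataset$spikes), n),
                  trial_id = 0L,
                  spike_time_s = unlist(dataset$spikes, use.names = FALSE))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read spike times from long-format CSV
#'
#' @param path CSV with columns `unit_id`, `spike_time_s` (a `trial_id`
#'   column is carried along if present).
#' @param protocol optional `protocol` the spikes are aligned to.
#' @return A `spike_dataset` (without ground truth).
#' @export
read_spikes_csv <- function(path, protocol = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "spike_time_s") %in% names(d)))
    stop("expected columns unit_id and spike_time_s")
  spikes <- lapply(split(d$spike_time_s, d$unit_id), sort)
  structure(list(spikes = spikes, truth = NULL, protocol = protocol,
                 dt = NA_real_, prep = NA_character_),
            class = "spike_dataset")
}

default_config <- function() {
  list(seed = 1,
       in_vivo = TRUE,
       fwhm_nm = 20,
       total_flux = 1e16,
       lambda_max = list(rod = 498, melanopsin = 480),
       spd_blue = NULL, spd_yellow = NULL, lens = NULL,
       background_log_mel = 14.3,
       contrasts = c(0.71, 0.51, 0.32, 0.11),
       step_s = 30, isi_s = 210, repeats = 14, adaptation_s = 600,
       include_protocol2 = FALSE, protocol2_repeats = 1,
       n_units = 50,
       class_fractions = list(mel_stepper = 0.28, irradiance_tracker = 0.17,
                              rod_only = 0.35, null = 0.20),
       prep = "cnga3_dlgn", param_jitter = 0.2,
       dt = 0.1, alpha = 0.05)
}

#' Run the full design / protocol / simulate / analyse pipeline
#'
#' Builds the silencing model, solves the contrast series, generates the
#' contrast-step protocol (and optionally the irradiance-ramp protocol),
#' simulates a synthetic population, classifies units, and writes all
#' artefacts plus a manifest to the output directory. Identical configuration
#' and seed give byte-identical outputs.
#'
#' @param config a configuration list (see `silentsub:::default_config()` for
#'   keys and defaults) or the path of a YAML file of overrides.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a list with the model, pairs, protocols, dataset(s) and
#'   the unit-response table.
#' @export
run_end_to_end <- function(config = list(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- default_grid()
  lens <- if (!is.null(cfg$lens)) read_spd(cfg$lens, grid, "transmission")
  blue <- if (!is.null(cfg$spd_blue)) read_spd(cfg$spd_blue, grid)
          else gaussian_spd(438, cfg$fwhm_nm, cfg$total_flux, grid)
  yellow <- if (!is.null(cfg$spd_yellow)) read_spd(cfg$spd_yellow, grid)
            else gaussian_spd(575, cfg$fwhm_nm, cfg$total_flux, grid)
  model <- silencing_model(blue, yellow,
    pigments = list(rod = photopigment("rod", cfg$lambda_max$rod, cfg$in_vivo),
                    melanopsin = photopigment("melanopsin", cfg$lambda_max$melanopsin,
                                              cfg$in_vivo)),
    lens = lens)
  bg <- background_for(model, cfg$background_log_mel)
  pairs <- contrast_series(model, bg, targets = cfg$contrasts)
  jsonlite::write_json(
    lapply(pairs, function(p) list(
      target_contrast = p$target_contrast,
      background = p$background[c("blue", "yellow", "nd")],
      step = p$step[c("blue", "yellow", "nd")],
      flux = lapply(p$fluxes, function(m) lapply(m, function(ir)
        list(flux = ir$flux, log10 = if (ir$flux > 0) log10(ir$flux) else NULL))),
      contrasts = as.list(p$contrasts))),
    file.path(outdir, "pairs.json"), auto_unbox = TRUE, digits = NA)
  p1 <- build_protocol1(pairs, step_s = cfg$step_s, isi_s = cfg$isi_s,
                        repeats = cfg$repeats, adaptation_s = cfg$adaptation_s,
                        seed = derive_seed(cfg$seed, "protocol1"))
  write_protocol_json(p1, file.path(outdir, "protocol1.json"))
  spec <- population_spec(cfg$n_units, unlist(cfg$class_fractions),
                          prep = cfg$prep,
                          seed = derive_seed(cfg$seed, "simulate"),
                          param_jitter = cfg$param_jitter)
  pop <- sample_population(spec)
  ds1 <- simulate_dataset(p1, spec, model, dt = cfg$dt, population = pop)
  write_spikes_csv(ds1, file.path(outdir, "spikes_protocol1.csv"))
  ds2 <- NULL
  if (isTRUE(cfg$include_protocol2)) {
    p2 <- repeat_protocol(build_protocol2(pairs[[1]]), cfg$protocol2_repeats)
    write_protocol_json(p2, file.path(outdir, "protocol2.json"))
    ds2 <- simulate_dataset(p2, spec, model, dt = cfg$dt, population = pop)
    write_spikes_csv(ds2, file.path(outdir, "spikes_protocol2.csv"))
  }
  responses <- classify_units(ds1, ds2, model = model, background = bg,
                              alpha = cfg$alpha)
  write.csv(responses, file.path(outdir, "unit_responses.csv"), row.names = FALSE)
  truth <- ds1$truth
  counts <- list(
    units = nrow(truth),
    responsive = sum(responses$class == "stepper"),
    trackers = sum(responses$class == "tracker"),
    excluded = sum(responses$excluded))
  manifest <- list(package = "silentsub",
                   version = as.character(utils::packageVersion("silentsub")),
                   config = cfg,
                   derived_seeds = list(protocol1 = derive_seed(cfg$seed, "protocol1"),
                                        simulate = derive_seed(cfg$seed, "simulate")),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(model = model, background = bg, pairs = pairs,
                 protocol1 = p1, dataset1 = ds1, dataset2 = ds2,
                 responses = responses, manifest = manifest))
}

#' Write example fixtures
#'
#' Writes the synthetic Gaussian LED spectra (438 and 575 nm), the lens
#' transmission template, an example YAML configuration and a small
#' pre-simulated spike dataset with its ground truth.
#'
#' @param outdir output directory.
#' @param seed seed for the example dataset.
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- default_grid()
  paths <- c(blue = file.path(outdir, "led_blue_438.csv"),
             yellow = file.path(outdir, "led_yellow_575.csv"),
             lens = file.path(outdir, "lens_transmission.csv"),
             config = file.path(outdir, "config.yaml"),
             protocol = file.path(outdir, "example_protocol1.json"),
             spikes = file.path(outdir, "example_spikes.csv"),
             truth = file.path(outdir, "example_truth.json"))
  write_spd(gaussian_spd(438, 20, 1e16, grid), paths[["blue"]])
  write_spd(gaussian_spd(575, 20, 1e16, grid), paths[["yellow"]])
  write_spd(lens_transmission(grid), paths[["lens"]])
  cfg <- list(seed = seed, n_units = 10, repeats = 4,
              contrasts = c(0.71, 0.38), isi_s = 90, adaptation_s = 120)
  yaml::write_yaml(cfg, paths[["config"]])
  model <- default_model()
  bg <- background_for(model, 14.3)
  pairs <- contrast_series(model, bg, targets = cfg$contrasts)
  p1 <- build_protocol1(pairs, isi_s = cfg$isi_s, repeats = cfg$repeats,
                        adaptation_s = cfg$adaptation_s,
                        seed = derive_seed(seed, "protocol1"))
  write_protocol_json(p1, paths[["protocol"]])
  spec <- population_spec(cfg$n_units, prep = "cnga3_dlgn",
                          seed = derive_seed(seed, "simulate"))
  ds <- simulate_dataset(p1, spec, model)
  write_spikes_csv(ds, paths[["spikes"]])
  jsonlite::write_json(ds$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
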