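# End-to-end orchestration: simulate -> preprocess -> spectral -> localize
# -> laterality, driven by one declarative config with explicit seeds, with
# every stage's parameters echoed into the run provenance.

#' Default run configuration
#'
#' Returns the full parameter set of a pipeline run as a nested list:
#' simulation (trials, durations, source, depth, noise), geometry (helmet,
#' sphere margin, grid spacing, IFG ROI), preprocessing (rates, notch,
#' band-stop, intercept), spectral (band, multitaper, bootstrap), source
#' reconstruction (windows, regularization, FDR) and laterality (thresholds,
#' bootstrap). Values mirror the covert-verb-generation protocol; override
#' any subset via `...` or a YAML/JSON file.
#'
#' @param ... named overrides, e.g. `simulation = list(n_trials = 20)`.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    schema = "opmlat-config-1",
    seed = 1L,
    simulation = list(
      source_pos = c(-53.26, 17.3, 19.03),
      amplitude_nAm = 20, depth = 0.4, n_trials = 120,
      task_s = 3, rest_s = 2, fs = 1000, noise_fT_rtHz = 15),
    geometry = list(
      n_scalp = 26, n_ref = 4, scalp_radius = 90, standoff = 6.5,
      sphere_margin = 15, grid_spacing = 5, grid_margin = 10,
      roi = list(IFG = list(center = c(-53.26, 17.3, 19.03), radius = 20,
                            mirror = TRUE))),
    preprocess = list(target_rate = 200, notch = 50, bandstop = c(75, 79),
                      intercept = TRUE),
    spectral = list(band = c(15, 30), rest_window = c(-2, 0),
                    task_window = c(0, 3), half_bandwidth = 1.5,
                    window_s = 1, step_s = 0.1, n_boot = 100),
    localize = list(baseline_window = c(-1, 0), active_window = c(0, 1),
                    regularization = 0.05, fdr_q = 0.05, filter_order = 5,
                    confvol_n_boot = 50),
    laterality = list(thresholds = seq(1, 15, length.out = 29), n_boot = 100))
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from YAML or JSON
#'
#' File values override the package defaults; unknown top-level keys raise a
#' validation error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_opmlat(sprintf("no such config: %s", path), "opmlat_io_error")
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop_opmlat(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")),
                "opmlat_validation_error")
  validate_config(utils::modifyList(base, user))
}

validate_config <- function(cfg) {
  problems <- character(0)
  sim <- cfg$simulation
  if (sim$depth < 0 || sim$depth > 1)
    problems <- c(problems, "simulation.depth outside [0, 1]")
  if (sim$n_trials < 1) problems <- c(problems, "simulation.n_trials < 1")
  sp <- cfg$spectral
  epoch <- c(-sim$rest_s, sim$task_s)
  for (nm in c("rest_window", "task_window")) {
    wdw <- sp[[nm]]
    if (wdw[1] < epoch[1] - 1e-9 || wdw[2] > epoch[2] + 1e-9)
      problems <- c(problems, sprintf("spectral.%s outside the epoch [%g, %g]",
                                      nm, epoch[1], epoch[2]))
  }
  for (nm in c("baseline_window", "active_window")) {
    wdw <- cfg$localize[[nm]]
    if (wdw[1] < epoch[1] - 1e-9 || wdw[2] > epoch[2] + 1e-9)
      problems <- c(problems, sprintf("localize.%s outside the epoch [%g, %g]",
                                      nm, epoch[1], epoch[2]))
  }
  if (max(sp$band) >= cfg$preprocess$target_rate / 2)
    problems <- c(problems, "spectral.band reaches the post-downsampling Nyquist")
  if (is.null(cfg$seed)) problems <- c(problems, "seed missing")
  if (length(problems))
    stop_opmlat(paste0("invalid config:\n  - ",
                       paste(problems, collapse = "\n  - ")),
                "opmlat_validation_error")
  cfg
}

#' Run the full lateralisation pipeline
#'
#' Executes geometry -> lead fields -> simulation -> preprocessing ->
#' sensor-level spectral analysis -> beamformer localisation -> confidence
#' volume -> laterality curve, writing `data.h5`, `clean.h5`,
#' `sensor_course.tsv`, `statmap.tsv`, `confidence_volume.json`,
#' `laterality.tsv`, `resolved-config.yaml` and `run.log` into `out_dir`.
#'
#' @param config a `run_config` list (see [default_config()]) or a path to a
#'   YAML/JSON config.
#' @param out_dir output directory (created; default a tempdir subdirectory).
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% file.path(tempdir(),
                                    paste0("opmlat-run-", format(Sys.time(), "%Y%m%d-%H%M%S")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop_opmlat(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), "opmlat_pipeline_error")
    })
    say("stage %s: done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    out
  }
  yaml::write_yaml(config, file.path(out_dir, "resolved-config.yaml"))

  geo <- config$geometry
  res <- list(config = config, out_dir = out_dir)
  res$array <- stage("geometry", {
    default_helmet(geo$n_scalp, geo$n_ref, scalp_radius = geo$scalp_radius,
                   standoff = geo$standoff,
                   sampling_rate = config$simulation$fs)
  })
  res$sphere <- stage("sphere_fit", {
    ## sensors sit standoff mm above the scalp, so the sensor-sphere radius
    ## minus (margin + standoff) recovers the inner-skull stand-in
    fit_conductor_sphere(res$array$positions[scalp_idx(res$array), ],
                         margin = geo$sphere_margin + geo$standoff)
  })
  res$grid <- stage("source_grid", {
    build_source_grid(res$sphere, spacing = geo$grid_spacing,
                      roi_specs = geo$roi, margin = geo$grid_margin)
  })
  res$leadfields <- stage("leadfields", {
    compute_leadfields(res$array, res$grid, res$sphere)
  })
  res$truth <- do.call(simulation_truth,
                       c(config$simulation, list(seed = config$seed)))
  res$raw <- stage("simulate", simulate_dataset(res$truth, res$array,
                                                res$leadfields))
  stage("write_raw", write_dataset(res$raw, file.path(out_dir, "data.h5")))
  pp <- config$preprocess
  sg <- stage("preprocess", {
    ds <- downsample_and_filter(res$raw, pp$target_rate, pp$notch, pp$bandstop)
    synthetic_gradiometry(ds, intercept = pp$intercept)
  })
  res$clean <- sg$ds
  res$interference_weights <- sg$weights
  stage("write_clean", write_dataset(res$clean, file.path(out_dir, "clean.h5")))
  sp <- config$spectral
  res$sensor_course <- stage("spectral", {
    spec <- multitaper_tf(res$clean, fmin = max(1, sp$band[1] - 5),
                          fmax = sp$band[2] + 5,
                          half_bandwidth = sp$half_bandwidth,
                          window_s = sp$window_s, step_s = sp$step_s)
    bootstrap_sensor_course(spec, sp$band, sp$rest_window,
                            n_boot = sp$n_boot, seed = config$seed)
  })
  res$max_sensor <- max_modulated_sensor(res$sensor_course, sp$task_window)
  say("max modulated sensor: %s (%.1f%%)", res$max_sensor$label,
      res$max_sensor$value)
  stage("write_sensor_course", {
    df <- data.frame(channel = rep(res$sensor_course$channel_labels,
                                   ncol(res$sensor_course$pct)),
                     time_s = rep(res$sensor_course$time,
                                  each = nrow(res$sensor_course$pct)),
                     pct = as.numeric(res$sensor_course$pct),
                     se = as.numeric(res$sensor_course$se),
                     significant = as.integer(res$sensor_course$significant))
    utils::write.table(format(df, digits = 10, trim = TRUE),
                       file.path(out_dir, "sensor_course.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  })
  lc <- config$localize
  res$filtered <- stage("band_filter",
                        band_filter(res$clean, sp$band, lc$filter_order))
  res$weights <- stage("lcmv", lcmv_weights(res$filtered, res$leadfields,
                                            lc$regularization))
  res$statmap <- stage("f_map", f_map(res$filtered, res$weights,
                                      lc$baseline_window, lc$active_window,
                                      band = sp$band, q = lc$fdr_q))
  stage("write_statmap", write_statmap(res$statmap,
                                       file.path(out_dir, "statmap.tsv")))
  res$confvol <- stage("confidence_volume", {
    confidence_volume(res$filtered, res$leadfields, "IFG_left",
                      n_boot = lc$confvol_n_boot, seed = config$seed,
                      baseline_window = lc$baseline_window,
                      active_window = lc$active_window,
                      regularization = lc$regularization)
  })
  jsonlite::write_json(list(roi = "IFG_left", n_boot = res$confvol$n_boot,
                            extent_mm = res$confvol$extent,
                            peaks = res$confvol$peaks),
                       file.path(out_dir, "confidence_volume.json"),
                       digits = NA, auto_unbox = TRUE)
  lat <- config$laterality
  res$li <- stage("laterality", {
    bootstrap_li(res$filtered, res$leadfields, "IFG_left", "IFG_right",
                 thresholds = lat$thresholds, n_boot = lat$n_boot,
                 seed = config$seed, baseline_window = lc$baseline_window,
                 active_window = lc$active_window,
                 regularization = lc$regularization)
  })
  stage("write_laterality", write_li_curve(res$li,
                                           file.path(out_dir, "laterality.tsv")))
  say("run complete: %s", out_dir)
  invisible(res)
}

#' Generate the canonical small test datasets
#'
#' Writes four scaled-down datasets (noiseless single source, null
#' depth-0, x-mirrored source, misspecified interference) plus a manifest
#' to `dir`. Regeneration is bit-identical for a fixed seed.
#'
#' @param seed base RNG seed.
#' @param dir output directory.
#' @param n_trials trials per fixture (default 20).
#' @return (invisibly) the manifest as a list.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("opmlat-fixtures-"),
                          n_trials = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  array <- default_helmet()
  sphere <- fit_conductor_sphere(array$positions[scalp_idx(array), ],
                                 margin = 15 + 6.5)
  grid <- build_source_grid(sphere, spacing = 20,
                            roi_specs = list(IFG = list(center = c(-53.26, 17.3, 19.03),
                                                        radius = 20)))
  lf <- compute_leadfields(array, grid, sphere)
  variants <- list(
    noiseless = list(depth = 0.4, noise_fT_rtHz = 0,
                     interference = list(low_amp = 0, line50_amp = 0,
                                         line77_amp = 0)),
    null = list(depth = 0),
    mirrored = list(depth = 0.4, source_pos = c(53.26, 17.3, 19.03)),
    misspecified = list(depth = 0.4,
                        interference = list(misspecified = TRUE)))
  manifest <- list(seed = seed, n_trials = n_trials, files = list())
  for (nm in names(variants)) {
    truth <- do.call(simulation_truth,
                     c(variants[[nm]],
                       list(n_trials = n_trials, seed = seed)))
    ds <- suppressWarnings(simulate_dataset(truth, array, lf))
    path <- file.path(dir, paste0(nm, ".h5"))
    write_dataset(ds, path)
    manifest$files[[nm]] <- list(file = basename(path), depth = truth$depth,
                                 n_trials = truth$n_trials)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
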