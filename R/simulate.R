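# Trial-epoched synthetic OPM recordings. The generator states the world the
# analysis assumes: a lateralized beta-band (15-30 Hz) source whose amplitude
# envelope drops during the task (event-related desynchronization),
# common-mode environmental interference with a rank-limited spatial
# structure sampled by both the scalp and the reference array, and white
# sensor noise. Defaults follow the covert-verb-generation protocol:
# 120 trials, 3 s task, ~2 s rest, 1000 Hz sampling, +/-1.5 nT dynamic range.

#' Simulation ground truth
#'
#' @param source_pos n x 3 matrix (or length-3 vector) of dipole positions
#'   (mm). Default: left inferior frontal gyrus peak reported for covert verb
#'   generation, (-53.26, 17.3, 19.03).
#' @param source_ori matching unit moment orientation(s); default a tangential
#'   direction (radial moments are silent in a spherical conductor).
#' @param amplitude_nAm baseline RMS source amplitude in nA m (default 20;
#'   chosen so the best sensor sees a few hundred fT, i.e. sensor-level
#'   percent changes of some tens of percent).
#' @param depth fractional amplitude reduction of the source envelope during
#'   the task, in `[0, 1]`; the band-power reduction is `1 - (1 - depth)^2`.
#' @param n_trials number of trials (default 120).
#' @param task_s,rest_s task and rest durations in seconds (default 3 and 2;
#'   epochs are cut as `[-rest_s, task_s]` around task onset).
#' @param ramp_s cosine ramp length of the envelope transition (default 0.2 s).
#' @param fs sampling rate Hz (default 1000).
#' @param band source pass-band in Hz (default `c(15, 30)`).
#' @param interference list of interference parameters: `n_low` random-walk
#'   components (< 10 Hz), their per-channel RMS `low_amp` (tesla), mains and
#'   sensor-modulation sinusoid amplitudes `line50_amp` / `line77_amp`
#'   (tesla), and `misspecified` (add a component invisible to the reference
#'   array).
#' @param noise_fT_rtHz white sensor-noise amplitude spectral density
#'   (default 15 fT/sqrt(Hz)).
#' @param seed integer RNG seed; recorded in the dataset.
#' @return an object of class `opm_truth`.
#' @export
simulation_truth <- function(source_pos = c(-53.26, 17.3, 19.03),
                             source_ori = NULL,
                             amplitude_nAm = 20,
                             depth = 0.4,
                             n_trials = 120,
                             task_s = 3, rest_s = 2, ramp_s = 0.2,
                             fs = 1000,
                             band = c(15, 30),
                             interference = list(),
                             noise_fT_rtHz = 15,
                             seed = 1L) {
  if (is.null(dim(source_pos))) source_pos <- matrix(source_pos, ncol = 3)
  if (depth < 0 || depth > 1)
    stop_opmlat("depth must lie in [0, 1]", "opmlat_config_error")
  if (n_trials < 1) stop_opmlat("need at least one trial", "opmlat_config_error")
  if (is.null(source_ori)) {
    source_ori <- t(apply(source_pos, 1, function(p) {
      v <- c(p[2], -p[1], 0)       # tangential w.r.t. a centred radial ray
      if (sum(v^2) < 1e-12) v <- c(1, 0, 0)
      v / sqrt(sum(v^2))
    }))
  }
  if (is.null(dim(source_ori))) source_ori <- matrix(source_ori, ncol = 3)
  source_ori <- source_ori / sqrt(rowSums(source_ori^2))
  idef <- list(n_low = 4, low_amp = 30e-12, line50_amp = 10e-12,
               line77_amp = 10e-12, misspecified = FALSE, misspec_amp = 10e-12)
  interference <- utils::modifyList(idef, interference)
  structure(list(source_pos = source_pos, source_ori = source_ori,
                 amplitude_nAm = amplitude_nAm, depth = depth,
                 n_trials = as.integer(n_trials), task_s = task_s,
                 rest_s = rest_s, ramp_s = ramp_s, fs = fs, band = band,
                 interference = interference,
                 noise_fT_rtHz = noise_fT_rtHz, seed = as.integer(seed)),
            class = "opm_truth")
}

## Envelope over the epoch [-rest_s, task_s]: 1 during rest, cosine ramp down
## to (1 - depth) over ramp_s after onset.
task_envelope <- function(time, depth, ramp_s) {
  env <- rep(1, length(time))
  lo <- 1 - depth
  in_ramp <- time > 0 & time < ramp_s
  env[in_ramp] <- lo + (1 - lo) * (1 + cos(pi * time[in_ramp] / ramp_s)) / 2
  env[time >= ramp_s] <- lo
  env
}

## Unit-RMS band-limited Gaussian process of length n at rate fs.
bandlimited_noise <- function(n, fs, band, order = 5) {
  cf <- butter_design(order, band, fs, "pass")
  x <- filtfilt_opm(cf, stats::rnorm(n))
  x / stats::sd(x)
}

## Slow (< cutoff Hz) unit-RMS drift: random walk, low-passed, detrended.
slow_drift <- function(n, fs, cutoff = 10) {
  w <- cumsum(stats::rnorm(n))
  cf <- butter_design(4, cutoff, fs, "low")
  x <- filtfilt_opm(cf, w)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(rep(0, n))
  x / s
}

#' Simulate a trial-epoched OPM dataset
#'
#' Per trial, the source time course is band-limited Gaussian noise whose
#' amplitude envelope drops by `truth$depth` during the task. Sensor data are
#' `leadfield x source + interference + white noise`; the interference has a
#' rank-`n_ref` spatial structure seen by both arrays, so a linear mixture of
#' the reference channels can reproduce (and hence remove) it exactly.
#' Samples exceeding the +/-1.5 nT dynamic range are flagged with a warning,
#' never silently clipped.
#'
#' @param truth an `opm_truth`.
#' @param array an `opm_sensor_array`.
#' @param leadfields an `opm_leadfields` (supplies the conductor sphere; the
#'   source lead field is evaluated analytically at the true position, which
#'   need not be a grid point).
#' @param keep_components if `TRUE`, attach the per-channel signal,
#'   interference and noise arrays plus the source time courses (used by
#'   oracle tests); a character subset of
#'   `c("signal", "interference", "noise", "source")` attaches only those.
#' @return an object of class `opm_trials`: `data` is a channels x samples x
#'   trials array (tesla), with `time` axis (s, task onset at 0), `fs`,
#'   `array`, `events`, `provenance` and the embedded `truth`.
#' @export
simulate_dataset <- function(truth, array, leadfields,
                             keep_components = FALSE) {
  fs <- truth$fs
  if (fs < 2 * max(truth$band, 77, 50))
    stop_opmlat("sampling rate below twice the highest synthesized frequency",
                "opmlat_config_error")
  time <- seq(-truth$rest_s, truth$task_s, by = 1 / fs)
  time <- time[-length(time)]                  # half-open epoch
  ns <- length(time)
  ## waveforms are synthesized on a padded time base and sliced to the
  ## epoch, emulating an excerpt from a continuous recording: per-trial
  ## band-pass generation would otherwise leave an in-band power deficit at
  ## the epoch edges (filter startup transients), which biases edge
  ## spectrogram windows under the null
  npad <- round(0.5 * fs)
  time_pad <- seq(-truth$rest_s - npad / fs, by = 1 / fs,
                  length.out = ns + 2 * npad)
  core <- (npad + 1):(npad + ns)
  si <- scalp_idx(array); ri <- ref_idx(array)
  if (length(ri) == 0L)
    stop_opmlat("array has no reference channels", "opmlat_validation_error")
  nch <- length(array$labels)
  set.seed(truth$seed)

  ## fixed spatial structure of the interference: n_comp temporal components
  ## with a rank-length(ri) spatial pattern; the scalp patterns are linear
  ## mixtures of the reference patterns by construction.
  icfg <- truth$interference
  n_comp <- icfg$n_low + 2L
  A_ref <- matrix(stats::rnorm(length(ri) * n_comp), length(ri), n_comp)
  Mix <- matrix(stats::rnorm(length(si) * length(ri)), length(si), length(ri)) /
    sqrt(length(ri))
  A_scalp <- Mix %*% A_ref
  amp <- c(rep(icfg$low_amp, icfg$n_low), icfg$line50_amp, icfg$line77_amp)
  misspec_pat <- if (isTRUE(icfg$misspecified))
    stats::rnorm(length(si)) else NULL

  ## source patterns: scalp-channel field per unit moment along each source's
  ## orientation (A m -> T)
  n_src <- nrow(truth$source_pos)
  pat <- vapply(seq_len(n_src), function(k) {
    as.numeric(leadfield_at(array, leadfields$sphere, truth$source_pos[k, ]) %*%
                 truth$source_ori[k, ])
  }, numeric(length(si)))
  env_pad <- task_envelope(time_pad, truth$depth, truth$ramp_s)
  amp_Am <- truth$amplitude_nAm * 1e-9
  noise_sd <- truth$noise_fT_rtHz * 1e-15 * sqrt(fs / 2)

  data <- array(0, dim = c(nch, ns, truth$n_trials))
  comp_names <- if (isTRUE(keep_components))
    c("signal", "interference", "noise", "source")
  else if (is.character(keep_components)) keep_components
  else character(0)
  comp <- if (length(comp_names)) {
    out <- lapply(comp_names, function(nm) {
      nrows <- if (nm == "source") n_src else length(si)
      array(0, dim = c(nrows, ns, truth$n_trials))
    })
    names(out) <- comp_names
    out
  } else NULL

  ns_pad <- ns + 2 * npad
  for (t in seq_len(truth$n_trials)) {
    src <- vapply(seq_len(n_src), function(k)
      (bandlimited_noise(ns_pad, fs, truth$band) * env_pad * amp_Am)[core],
      numeric(ns))
    sig <- pat %*% t(src)
    basis <- cbind(
      vapply(seq_len(icfg$n_low), function(k) slow_drift(ns_pad, fs)[core],
             numeric(ns)),
      sqrt(2) * sin(2 * pi * 50 * (time + truth$rest_s) + stats::runif(1, 0, 2 * pi)),
      sqrt(2) * sin(2 * pi * 77 * (time + truth$rest_s) + stats::runif(1, 0, 2 * pi)))
    basis <- sweep(basis, 2, amp, "*")
    int_scalp <- A_scalp %*% t(basis)
    int_ref <- A_ref %*% t(basis)
    if (!is.null(misspec_pat))
      int_scalp <- int_scalp +
        misspec_pat %*% t(slow_drift(ns_pad, fs)[core] * icfg$misspec_amp)
    noi <- matrix(stats::rnorm(nch * ns, sd = noise_sd), nch, ns)
    data[si, , t] <- sig + int_scalp + noi[si, ]
    data[ri, , t] <- int_ref + noi[ri, ]
    if ("signal" %in% comp_names) comp$signal[, , t] <- sig
    if ("interference" %in% comp_names) comp$interference[, , t] <- int_scalp
    if ("noise" %in% comp_names) comp$noise[, , t] <- noi[si, ]
    if ("source" %in% comp_names) comp$source[, , t] <- t(src)
  }
  over <- abs(data) > 1.5e-9
  if (any(over)) {
    ix <- which(over, arr.ind = TRUE)
    warn_opmlat(sprintf(
      "%d samples exceed the +/-1.5 nT dynamic range (first: channel %d, trial %d); values are kept, not clipped",
      sum(over), ix[1, 1], ix[1, 3]), "opmlat_dynamic_range_warning")
  }
  ds <- structure(list(data = data, fs = fs, time = time, array = array,
                       events = data.frame(trial = seq_len(truth$n_trials),
                                           onset_s = 0, offset_s = truth$task_s),
                       truth = truth, stage = "raw",
                       provenance = list(prov_record("simulate", list(
                         seed = truth$seed, n_trials = truth$n_trials,
                         depth = truth$depth,
                         amplitude_nAm = truth$amplitude_nAm)))),
                  class = "opm_trials")
  if (!is.null(comp)) attr(ds, "components") <- comp
  ds
}

#' @export
print.opm_trials <- function(x, ...) {
  cat(sprintf("<opm_trials> %d channels x %d samples x %d trials @ %g Hz [%s], t in [%.3g, %.3g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$stage,
              min(x$time), max(x$time)))
  invisible(x)
}

DATASET_SCHEMA <- "opmlat-trialdataset-1"

#' Write / read a trial dataset (HDF5 container)
#'
#' The container stores `/data` (channels x samples x trials, float64 tesla),
#' `/time`, `/fs`, `/events`, a `/channels` table, `/provenance` (JSON),
#' `/truth` (JSON, when the dataset is simulated) and `/schema`. Round trips
#' are bit-exact on the data array.
#'
#' @param ds an `opm_trials`.
#' @param path HDF5 file path (overwritten).
#' @export
write_dataset <- function(ds, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(ds$data, path, "data")
  rhdf5::h5write(ds$time, path, "time")
  rhdf5::h5write(ds$fs, path, "fs")
  rhdf5::h5write(ds$stage, path, "stage")
  rhdf5::h5write(DATASET_SCHEMA, path, "schema")
  rhdf5::h5write(ds$events, path, "events")
  ch <- data.frame(label = ds$array$labels,
                   x_mm = ds$array$positions[, 1],
                   y_mm = ds$array$positions[, 2],
                   z_mm = ds$array$positions[, 3],
                   ox = ds$array$orientations[, 1],
                   oy = ds$array$orientations[, 2],
                   oz = ds$array$orientations[, 3],
                   role = ds$array$role, stringsAsFactors = FALSE)
  rhdf5::h5write(ch, path, "channels")
  rhdf5::h5write(as.character(jsonlite::toJSON(ds$provenance, digits = NA,
                                               auto_unbox = TRUE)),
                 path, "provenance")
  if (!is.null(ds$truth))
    rhdf5::h5write(as.character(jsonlite::toJSON(unclass(ds$truth), digits = NA,
                                                 auto_unbox = TRUE)),
                   path, "truth")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop_opmlat(sprintf("no such file: %s", path), "opmlat_io_error")
  schema <- tryCatch({
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    as.character(rhdf5::h5read(path, "schema"))
  }, error = function(e)
    stop_opmlat(sprintf("not a readable opmlat container (%s): %s",
                        path, conditionMessage(e)), "opmlat_schema_error"))
  if (!identical(schema, DATASET_SCHEMA))
    stop_opmlat(sprintf("container schema '%s' != expected '%s'",
                        schema, DATASET_SCHEMA), "opmlat_schema_error")
  ch <- rhdf5::h5read(path, "channels")
  arr <- sensor_array(as.character(ch$label),
                      cbind(ch$x_mm, ch$y_mm, ch$z_mm),
                      cbind(ch$ox, ch$oy, ch$oz),
                      as.character(ch$role),
                      sampling_rate = as.numeric(rhdf5::h5read(path, "fs")))
  prov <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "provenance")),
                             simplifyVector = FALSE)
  truth <- NULL
  if ("truth" %in% rhdf5::h5ls(path)$name) {
    tl <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "truth")),
                             simplifyVector = TRUE)
    tl$source_pos <- matrix(tl$source_pos, ncol = 3)
    tl$source_ori <- matrix(tl$source_ori, ncol = 3)
    truth <- structure(tl, class = "opm_truth")
  }
  structure(list(data = rhdf5::h5read(path, "data"),
                 fs = as.numeric(rhdf5::h5read(path, "fs")),
                 time = as.numeric(rhdf5::h5read(path, "time")),
                 array = arr,
                 events = as.data.frame(rhdf5::h5read(path, "events")),
                 truth = truth,
                 stage = as.character(rhdf5::h5read(path, "stage")),
                 provenance = prov),
            class = "opm_trials")
}
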