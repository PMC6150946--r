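# Shared fixtures, built in code. Everything here is deterministic given the
# seeds passed at call sites; datasets are kept small (few trials, coarse
# grids) so the default run stays fast.

fix_helmet <- function(fs = 1000) default_helmet(sampling_rate = fs)

fix_sphere <- function(array = fix_helmet()) {
  # sensors sit 6.5 mm above a 90 mm scalp; 15 mm scalp-to-inner-skull margin
  fit_conductor_sphere(array$positions[array$role == "scalp", ],
                       margin = 15 + 6.5)
}

fix_grid <- function(sphere = fix_sphere(), spacing = 20) {
  build_source_grid(sphere, spacing = spacing,
                    roi_specs = list(IFG = list(center = c(-53.26, 17.3, 19.03),
                                                radius = 20)))
}

fix_leadfields <- function(array = fix_helmet(), spacing = 20) {
  sphere <- fix_sphere(array)
  compute_leadfields(array, fix_grid(sphere, spacing), sphere)
}

## Small simulated dataset; variant mirrors make_fixtures().
fix_dataset <- function(n_trials = 12, seed = 42L, variant = "default",
                        lf = NULL, keep_components = FALSE, ...) {
  array <- fix_helmet()
  lf <- lf %||% fix_leadfields(array)
  over <- switch(variant,
    default = list(),
    noiseless = list(noise_fT_rtHz = 0,
                     interference = list(low_amp = 0, line50_amp = 0,
                                         line77_amp = 0)),
    null = list(depth = 0),
    mirrored = list(source_pos = c(53.26, 17.3, 19.03)),
    misspecified = list(interference = list(misspecified = TRUE)),
    stop("unknown variant"))
  truth <- do.call(simulation_truth,
                   utils::modifyList(c(over, list(n_trials = n_trials,
                                                  seed = seed)), list(...)))
  ds <- suppressWarnings(simulate_dataset(truth, array, lf,
                                          keep_components = keep_components))
  list(ds = ds, truth = truth, array = array, lf = lf)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## RMS helper
rms <- function(x) sqrt(mean(x^2))

## minimal dataset wrapper around a channels x samples x trials array
mk_ds <- function(data, fs, array) {
  structure(list(data = data, fs = fs,
                 time = seq(0, by = 1 / fs, length.out = dim(data)[2]),
                 array = array, stage = "raw", provenance = list()),
            class = "opm_trials")
}

## tiny array: ns scalp + nr reference channels at valid positions
mk_array <- function(ns, nr, fs = 1000) {
  n <- ns + nr
  az <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  pos <- cbind(120 * cos(az), 120 * sin(az), 40)
  ori <- cbind(cos(az), sin(az), 0)
  sensor_array(sprintf("C%02d", seq_len(n)), pos, ori,
               c(rep("scalp", ns), rep("reference", nr)), sampling_rate = fs)
}

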