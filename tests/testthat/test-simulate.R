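# Synthetic-data generator: construction properties, the component-wise
# power oracle, reproducibility, and container round trips.

test_that("noiseless single-source data are rank one per trial", {
  fx <- fix_dataset(n_trials = 3, seed = 2, variant = "noiseless")
  si <- which(fx$array$role == "scalp")
  for (t in 1:3) {
    Y <- fx$ds$data[si, , t]
    sv <- svd(Y)$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
  # and the dataset records its seed and truth
  expect_identical(fx$ds$truth$seed, 2L)
})

test_that("null simulations have equal task and rest beta power in expectation", {
  fx <- fix_dataset(n_trials = 60, seed = 3, variant = "null",
                    keep_components = TRUE)
  comp <- attr(fx$ds, "components")
  best <- which.max(apply(comp$signal[, , 1], 1, function(r) max(abs(r))))
  rest_i <- fx$ds$time < 0
  task_i <- fx$ds$time >= 0.3          # clear of the onset ramp
  ratios <- vapply(seq_len(60), function(t) {
    s <- comp$signal[best, , t]
    stats::var(s[task_i]) / stats::var(s[rest_i])
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(60)
  expect_lt(abs(mean(ratios) - 1), 3 * se)
})

test_that("depth-0.4 sensor percent change matches the component-wise oracle", {
  fx <- fix_dataset(n_trials = 40, seed = 4, keep_components = TRUE)
  comp <- attr(fx$ds, "components")
  ## pipeline value: preprocess (which removes the interference), multitaper,
  ## percent change from rest, averaged over the task window
  clean <- synthetic_gradiometry(downsample_and_filter(fx$ds))$ds
  spec <- multitaper_tf(clean, fmin = 10, fmax = 35)
  pc <- percent_change(spec, band = c(15, 30), rest_window = c(-2, 0))
  si <- which(fx$array$role == "scalp")
  best <- which.max(apply(comp$signal[, , 1], 1, function(r) max(abs(r))))
  tidx <- pc$time >= 0.5 & pc$time <= 2.5       # clear of ramp and window edges
  pct_observed <- mean(pc$pct[best, tidx])
  ## oracle: -(1 - (1-depth)^2) * 100 * (signal share of in-band variance),
  ## from the stored signal and noise components (interference is removed by
  ## the regression, so it does not enter the share)
  rest_i <- which(fx$ds$time < 0)
  sig <- mean(vapply(1:40, function(t)
    fft_band_var(comp$signal[best, rest_i, t], fx$ds$fs, c(15, 30)), numeric(1)))
  noi <- mean(vapply(1:40, function(t)
    fft_band_var(comp$noise[best, rest_i, t], fx$ds$fs, c(15, 30)), numeric(1)))
  share <- sig / (sig + noi)
  pct_oracle <- -(1 - (1 - 0.4)^2) * 100 * share
  expect_lt(abs(pct_observed - pct_oracle), 5)
  # the signal share at the best sensor is substantial at default SNR
  expect_gt(share, 0.5)
})

test_that("interference lies exactly in the reference span when noise is zero", {
  fx <- fix_dataset(n_trials = 3, seed = 5, noise_fT_rtHz = 0,
                    keep_components = TRUE)
  comp <- attr(fx$ds, "components")
  ri <- which(fx$array$role == "reference")
  for (t in 1:3) {
    X <- t(fx$ds$data[ri, , t])                 # noise-free references
    P <- X %*% solve(crossprod(X), t(X))        # projector onto ref span
    I_sc <- t(comp$interference[, , t])
    resid <- I_sc - P %*% I_sc
    expect_lt(max(abs(resid)) / max(abs(I_sc)), 1e-10)
  }
})

test_that("left-hemisphere source modulates left sensors more than right", {
  fx <- fix_dataset(n_trials = 40, seed = 6)
  ## interference drift is nonstationary and seed-dependent, so the
  ## hemisphere contrast is evaluated on gradiometry-cleaned data, as in
  ## the analysis chain
  clean <- synthetic_gradiometry(downsample_and_filter(fx$ds))$ds
  arr <- fx$array
  si <- which(arr$role == "scalp")
  left <- arr$positions[si, 1] < 0
  rest_i <- clean$time < 0
  task_i <- clean$time >= 0.3
  ## per-trial beta modulation depth per channel, hemisphere-averaged
  mod <- function(ch) vapply(seq_len(40), function(t) {
    y <- clean$data[si[ch], , t]
    1 - fft_band_var(y[task_i], clean$fs, c(15, 30)) /
      fft_band_var(y[rest_i], clean$fs, c(15, 30))
  }, numeric(1))
  dl <- rowMeans(vapply(which(left), mod, numeric(40)))
  dr <- rowMeans(vapply(which(!left), mod, numeric(40)))
  tt <- stats::t.test(dl, dr, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("equal seeds give identical datasets and containers; IO round-trips", {
  arr <- fix_helmet()
  lf <- fix_leadfields(arr, spacing = 30)
  tr <- simulation_truth(n_trials = 3, seed = 9)
  d1 <- simulate_dataset(tr, arr, lf)
  d2 <- simulate_dataset(tr, arr, lf)
  expect_identical(d1$data, d2$data)
  f1 <- tempfile(fileext = ".h5"); f2 <- tempfile(fileext = ".h5")
  write_dataset(d1, f1); write_dataset(d2, f2)
  ## container content is deterministic (HDF5 headers embed timestamps, so
  ## raw bytes can differ across seconds; the decoded payload cannot)
  expect_identical(read_dataset(f1)$data, read_dataset(f2)$data)
  back <- read_dataset(f1)
  expect_identical(back$data, d1$data)          # bit-exact
  expect_equal(back$time, d1$time)
  expect_identical(back$array$labels, arr$labels)
  expect_equal(back$truth$depth, tr$depth)
  # truncated container: versioned error, not a crash
  raw <- readBin(f1, "raw", 512)
  f3 <- tempfile(fileext = ".h5")
  writeBin(raw, f3)
  expect_error(read_dataset(f3), class = "opmlat_schema_error")
})

test_that("truth validation and dynamic-range flagging work", {
  expect_error(simulation_truth(depth = 1.4), class = "opmlat_config_error")
  expect_error(simulation_truth(n_trials = 0), class = "opmlat_config_error")
  arr <- fix_helmet()
  lf <- fix_leadfields(arr, spacing = 30)
  hot <- simulation_truth(n_trials = 1, seed = 1,
                          interference = list(low_amp = 2e-9))
  expect_warning(simulate_dataset(hot, arr, lf),
                 class = "opmlat_dynamic_range_warning")
})
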