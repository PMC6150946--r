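# Preprocessing: notch / band-stop filtering, anti-aliased decimation, and
# per-trial synthetic gradiometry (regressing the reference array out of the
# scalp array via the Moore-Penrose pseudoinverse).

## Apply a zero-phase filter along the sample dimension of a
## channels x samples x trials array.
filter_trials <- function(data, coefs) {
  d <- dim(data)
  x <- matrix(aperm(data, c(2, 1, 3)), d[2], d[1] * d[3])
  x <- filtfilt_opm(coefs, x)
  aperm(array(x, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Downsample and filter a trial dataset
#'
#' Zero-phase 50 Hz notch and 75-79 Hz band-stop (the aliased sensor
#' modulation line sits at 77 Hz) applied at the original rate, followed by
#' an anti-aliasing low-pass and integer-factor decimation. All designs and
#' parameters are appended to the provenance log.
#'
#' @param ds an `opm_trials`.
#' @param target_rate target sampling rate Hz (must divide `ds$fs`).
#' @param notch_freqs centre frequencies of 2nd-order notch filters
#'   (`Q = 35`); default 50 Hz. `NULL` disables.
#' @param bandstop length-2 stop-band in Hz for the 4th-order Butterworth
#'   band-stop; default `c(75, 79)`. `NULL` disables.
#' @param antialias_frac anti-alias low-pass cutoff as a fraction of the
#'   target Nyquist (default 0.8, i.e. 80 Hz for 200 Hz output).
#' @return the filtered, decimated `opm_trials`.
#' @export
downsample_and_filter <- function(ds, target_rate = 200, notch_freqs = 50,
                                  bandstop = c(75, 79), antialias_frac = 0.8) {
  fs <- ds$fs
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop_opmlat(sprintf("target rate %g Hz must divide the sampling rate %g Hz",
                        target_rate, fs), "opmlat_config_error")
  fac <- as.integer(round(fac))
  for (f0 in notch_freqs) {
    if (f0 >= fs / 2)
      stop_opmlat(sprintf("notch at %g Hz is at/above Nyquist %g Hz", f0, fs / 2),
                  "opmlat_config_error")
    ds$data <- filter_trials(ds$data, notch_design(f0, Q = 35, fs))
  }
  if (!is.null(bandstop)) {
    if (max(bandstop) >= fs / 2)
      stop_opmlat("band-stop edge at/above Nyquist", "opmlat_config_error")
    ds$data <- filter_trials(ds$data, butter_design(4, bandstop, fs, "stop"))
  }
  if (fac > 1L) {
    ds$data <- filter_trials(ds$data,
                             butter_design(6, antialias_frac * target_rate / 2,
                                           fs, "low"))
    keep <- seq(1, dim(ds$data)[2], by = fac)
    ds$data <- ds$data[, keep, , drop = FALSE]
    ds$time <- ds$time[keep]
    ds$fs <- target_rate
    ds$array$sampling_rate <- target_rate
  }
  ds$stage <- "preprocessed"
  append_prov(ds, "downsample_and_filter",
              list(target_rate = target_rate, notch = notch_freqs,
                   notch_Q = 35, bandstop = bandstop,
                   antialias_Hz = antialias_frac * target_rate / 2,
                   order = "filters before decimation"))
}

#' Per-trial synthetic gradiometry
#'
#' For each trial, regresses the reference channels (plus an intercept by
#' default) out of every scalp channel: `beta_t = pinv(X_t) Y_t`,
#' `Y_t <- Y_t - X_t beta_t`, where `X_t` is samples x (references
#' [+ intercept]). Fitting per trial absorbs non-stationarity of the
#' interference over the recording. Reference channels are retained in the
#' dataset but marked consumed in provenance.
#'
#' @param ds an `opm_trials` with at least one reference channel.
#' @param intercept include an intercept column in the design (default TRUE).
#' @return a list with elements `ds` (cleaned dataset) and `weights`
#'   (class `opm_interference_weights`: per-trial coefficient matrices and
#'   per-channel variance explained).
#' @export
synthetic_gradiometry <- function(ds, intercept = TRUE) {
  si <- scalp_idx(ds$array); ri <- ref_idx(ds$array)
  if (length(ri) == 0L)
    stop_opmlat("no reference channels in dataset", "opmlat_validation_error")
  d <- dim(ds$data)
  ncolX <- length(ri) + as.integer(intercept)
  if (d[2] <= ncolX)
    stop_opmlat("fewer samples per trial than regressors", "opmlat_config_error")
  W <- vector("list", d[3])
  ve <- matrix(NA_real_, length(si), d[3])
  for (t in seq_len(d[3])) {
    X <- t(matrix(ds$data[ri, , t], nrow = length(ri)))
    if (intercept) X <- cbind(1, X)
    Y <- t(matrix(ds$data[si, , t], nrow = length(si)))
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
    pos <- sv$d > tol
    if (sum(pos) < ncolX)
      warn_opmlat(sprintf("rank-deficient reference design in trial %d (rank %d of %d)",
                          t, sum(pos), ncolX), "opmlat_rank_warning")
    beta <- if (any(pos))
      sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    else matrix(0, ncolX, ncol(Y))
    resid <- Y - X %*% beta
    v0 <- apply(Y, 2, stats::var)
    v1 <- apply(resid, 2, stats::var)
    ve[, t] <- ifelse(v0 > 0, pmin(pmax(1 - v1 / v0, 0), 1), 0)
    W[[t]] <- beta
    ds$data[si, , t] <- t(resid)
  }
  ds$stage <- "preprocessed"
  ds <- append_prov(ds, "synthetic_gradiometry",
                    list(intercept = intercept, n_ref = length(ri),
                         references = "consumed"))
  weights <- structure(list(beta = W, variance_explained = ve,
                            intercept = intercept,
                            ref_labels = ds$array$labels[ri],
                            scalp_labels = ds$array$labels[si]),
                       class = "opm_interference_weights")
  list(ds = ds, weights = weights)
}

#' @export
print.opm_interference_weights <- function(x, ...) {
  cat(sprintf("<opm_interference_weights> %d trials, %d references%s; median variance explained %.3f\n",
              length(x$beta), length(x$ref_labels),
              if (x$intercept) " + intercept" else "",
              stats::median(x$variance_explained)))
  invisible(x)
}
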