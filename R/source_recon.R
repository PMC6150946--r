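# Scalar LCMV beamforming. The data covariance is pooled over whole-epoch,
# band-filtered trials; each grid point gets the source orientation of
# maximal projected power (generalized eigenvector) and unit-gain weights
# w = C^-1 L theta / (theta' L' C^-1 L theta). The statistical map contrasts
# beamformed band power between an active and a baseline window as a
# per-point F ratio, reported two-sided on log F and thresholded with
# Benjamini-Hochberg FDR.

#' Band-pass filter a trial dataset
#'
#' Forward-backward (zero-phase) Butterworth band-pass of the given order,
#' applied to every channel.
#'
#' @param ds an `opm_trials`.
#' @param band length-2 pass-band in Hz (default `c(15, 30)`).
#' @param order filter order (default 5).
#' @return the filtered `opm_trials`.
#' @export
band_filter <- function(ds, band = c(15, 30), order = 5) {
  if (max(band) >= ds$fs / 2)
    stop_opmlat(sprintf("band edge %g Hz at/above Nyquist %g Hz",
                        max(band), ds$fs / 2), "opmlat_config_error")
  ds$data <- filter_trials(ds$data, butter_design(order, band, ds$fs, "pass"))
  ds$stage <- "band_filtered"
  append_prov(ds, "band_filter", list(band = band, order = order,
                                      design = "bidirectional Butterworth"))
}

## Per-trial scatter (covariance) matrices of the scalp channels over a time
## window, returned vectorized as an (nch^2) x trials matrix.
trial_scatter_vec <- function(ds, window = NULL) {
  si <- scalp_idx(ds$array)
  idx <- if (is.null(window)) seq_along(ds$time)
         else axis_window_idx(ds$time, window)
  d3 <- dim(ds$data)[3]
  nch <- length(si)
  out <- matrix(NA_real_, nch * nch, d3)
  for (t in seq_len(d3)) {
    Y <- matrix(ds$data[si, idx, t], nch, length(idx))
    Y <- Y - rowMeans(Y)
    out[, t] <- as.numeric(tcrossprod(Y) / (length(idx) - 1))
  }
  out
}

## Orientation of maximal power and unit-gain weights for one lead field
## L (nch x 3) given the inverse covariance Ci. The lead field of a spherical
## conductor has (numerical) rank 2; directions below rank_tol of the largest
## singular value are excluded before the generalized eigenproblem so the
## silent radial direction cannot be selected.
lcmv_point_solve <- function(Ci, L, rank_tol = 1e-6) {
  sv <- svd(L)
  r <- sum(sv$d > rank_tol * sv$d[1])
  if (r == 0) return(list(w = rep(0, nrow(L)), ori = c(NA, NA, NA),
                          power = NA_real_))
  V <- sv$v[, seq_len(r), drop = FALSE]
  Lr <- L %*% V
  M <- crossprod(Lr, Ci %*% Lr)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  th_r <- ev$vectors[, r]          # smallest eigenvalue -> maximal power
  theta <- as.numeric(V %*% th_r)
  theta <- theta / sqrt(sum(theta^2))
  Lt <- as.numeric(L %*% theta)
  denom <- as.numeric(crossprod(Lt, Ci %*% Lt))
  w <- as.numeric(Ci %*% Lt) / denom
  nz <- which(abs(w) > 0)[1]       # fix the physical +/- sign ambiguity
  if (!is.na(nz) && w[nz] < 0) { w <- -w; theta <- -theta }
  list(w = w, ori = theta, power = 1 / denom)
}

#' Compute scalar LCMV beamformer weights
#'
#' The covariance window covers the whole (band-filtered) epoch, pooled over
#' all trials; `regularization * mean(diag(C))` is added to the diagonal.
#'
#' @param ds_filtered a band-filtered `opm_trials`.
#' @param lf an `opm_leadfields` over the target grid.
#' @param regularization diagonal loading as a fraction of the mean sensor
#'   variance (default 0.05). With 0 a singular covariance raises a
#'   conditioning error.
#' @return an object of class `opm_bf_weights`: `W` (points x channels),
#'   `ori` (points x 3), noise-projected `power`, the regularized covariance
#'   and a conditioning report.
#' @export
lcmv_weights <- function(ds_filtered, lf, regularization = 0.05) {
  S <- trial_scatter_vec(ds_filtered)
  nch <- dim(lf$L)[1]
  C <- matrix(rowMeans(S), nch, nch)
  Creg <- C + regularization * mean(diag(C)) * diag(nch)
  eg <- eigen(Creg, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) <= max(eg) * .Machine$double.eps * nch)
    stop_opmlat("covariance is singular: set a nonzero regularization",
                "opmlat_conditioning_error")
  Ci <- chol2inv(chol(Creg))
  np <- dim(lf$L)[3]
  W <- matrix(NA_real_, np, nch)
  ori <- matrix(NA_real_, np, 3)
  pw <- numeric(np)
  for (p in seq_len(np)) {
    sol <- lcmv_point_solve(Ci, lf$L[, , p])
    W[p, ] <- sol$w; ori[p, ] <- sol$ori; pw[p] <- sol$power
  }
  structure(list(W = W, ori = ori, power = pw, grid = lf$grid,
                 channels = lf$channels, C = C, Creg = Creg, Ci = Ci,
                 regularization = regularization,
                 conditioning = list(eig_range = range(eg),
                                     spread = max(eg) / min(eg))),
            class = "opm_bf_weights")
}

#' @export
print.opm_bf_weights <- function(x, ...) {
  cat(sprintf("<opm_bf_weights> %d grid points x %d channels, reg %.3g, cond %.3g\n",
              nrow(x$W), ncol(x$W), x$regularization, x$conditioning$spread))
  invisible(x)
}

## F statistics (active/baseline beamformed band-power ratio) for a weight
## matrix given vectorized window scatters averaged over trials.
fstat_for_weights <- function(W, sb_mean, sa_mean) {
  nch <- ncol(W)
  WW <- t(vapply(seq_len(nrow(W)), function(p) as.numeric(tcrossprod(W[p, ])),
                 numeric(nch * nch)))
  vb <- as.numeric(WW %*% sb_mean)
  va <- as.numeric(WW %*% sa_mean)
  list(vb = vb, va = va, Fraw = va / vb)
}

#' Map beta-power change as a per-point F statistic
#'
#' Per grid point the beamformed band power (variance of the virtual
#' channel) is computed per trial in the baseline and active windows;
#' `F_raw` is the ratio of trial means. The map is two-sided on
#' `log F`: the reported `F` is `max(F_raw, 1/F_raw)` with `sign` +1 for
#' power increases and -1 for decreases (a desynchronization). P values use
#' an F reference distribution with `dof = n_trials * 2 * B * T` per window
#' (spectral degrees-of-freedom counting for band-limited data; the choice
#' is a package convention, exposed via `dof`), and FDR control is
#' Benjamini-Hochberg at level `q`.
#'
#' @param ds_filtered the band-filtered `opm_trials` used for `w`.
#' @param w an `opm_bf_weights`.
#' @param baseline_window,active_window equal-length time intervals (s);
#'   defaults: final second of rest `c(-1, 0)` and first task second
#'   `c(0, 1)`.
#' @param band the analysis band (Hz), used only for the dof convention.
#' @param q FDR level (default 0.05).
#' @param dof optional explicit degrees of freedom per window.
#' @return an object of class `opm_statmap`: data frame `map` with columns
#'   `x, y, z, F, sign, logF, p, fdr_pass`, plus window/dof metadata.
#' @export
f_map <- function(ds_filtered, w, baseline_window = c(-1, 0),
                  active_window = c(0, 1), band = c(15, 30), q = 0.05,
                  dof = NULL) {
  if (abs(diff(baseline_window) - diff(active_window)) > 1e-9)
    stop_opmlat("baseline and active windows must have equal length",
                "opmlat_config_error")
  sb <- rowMeans(trial_scatter_vec(ds_filtered, baseline_window))
  sa <- rowMeans(trial_scatter_vec(ds_filtered, active_window))
  fs_ <- fstat_for_weights(w$W, sb, sa)
  ## points with an all-zero weight vector (magnetically silent, e.g. the
  ## sphere centre) get NA, not a spurious ratio
  silent <- rowSums(abs(w$W)) == 0
  fs_$Fraw[silent] <- NA_real_
  if (any(fs_$vb <= 0 & !silent))
    stop_opmlat(sprintf("zero baseline variance at grid point %d",
                        which(fs_$vb <= 0 & !silent)[1]),
                "opmlat_degenerate_error")
  n_tr <- dim(ds_filtered$data)[3]
  dof <- dof %||% (n_tr * 2 * diff(band) * diff(active_window))
  p_lo <- stats::pf(fs_$Fraw, dof, dof)
  p <- pmin(2 * pmin(p_lo, 1 - p_lo), 1)
  p <- pmax(p, .Machine$double.xmin)
  pass <- stats::p.adjust(p, method = "BH") <= q
  pass[is.na(pass)] <- FALSE
  map <- data.frame(x = w$grid$points[, 1], y = w$grid$points[, 2],
                    z = w$grid$points[, 3],
                    F = pmax(fs_$Fraw, 1 / fs_$Fraw),
                    sign = ifelse(fs_$Fraw >= 1, 1, -1),
                    logF = log(fs_$Fraw),
                    p = p, fdr_pass = pass)
  structure(list(map = map, grid = w$grid, q = q, dof = dof,
                 baseline_window = baseline_window,
                 active_window = active_window, band = band),
            class = "opm_statmap")
}

#' @export
print.opm_statmap <- function(x, ...) {
  pk <- which.max(x$map$F)
  cat(sprintf("<opm_statmap> %d points; peak F = %.2f (%s) at (%.1f, %.1f, %.1f) mm; %d FDR-passing at q = %g\n",
              nrow(x$map), x$map$F[pk],
              if (x$map$sign[pk] < 0) "decrease" else "increase",
              x$map$x[pk], x$map$y[pk], x$map$z[pk],
              sum(x$map$fdr_pass), x$q))
  invisible(x)
}

#' Export a statistical map as TSV
#'
#' Columns: `x, y, z, F, sign, logF, p, fdr_pass`.
#' @param map an `opm_statmap`.
#' @param path output TSV.
#' @export
write_statmap <- function(map, path) {
  df <- map$map
  df$fdr_pass <- as.integer(df$fdr_pass)
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Shared bootstrap machinery: precompute per-trial scatters once, then
## refit covariance -> orientations -> weights -> F for any trial resample,
## restricted to a point subset.
bf_boot_machine <- function(ds_filtered, lf, point_idx, baseline_window,
                            active_window, regularization) {
  list(S_all = trial_scatter_vec(ds_filtered),
       S_b = trial_scatter_vec(ds_filtered, baseline_window),
       S_a = trial_scatter_vec(ds_filtered, active_window),
       L = lf$L[, , point_idx, drop = FALSE],
       nch = dim(lf$L)[1],
       reg = regularization,
       point_idx = point_idx)
}

bf_boot_fstat <- function(mach, trials) {
  C <- matrix(rowMeans(mach$S_all[, trials, drop = FALSE]), mach$nch, mach$nch)
  Creg <- C + mach$reg * mean(diag(C)) * diag(mach$nch)
  Ci <- chol2inv(chol(Creg))
  np <- dim(mach$L)[3]
  W <- matrix(NA_real_, np, mach$nch)
  for (p in seq_len(np)) W[p, ] <- lcmv_point_solve(Ci, mach$L[, , p])$w
  fs_ <- fstat_for_weights(W,
                           rowMeans(mach$S_b[, trials, drop = FALSE]),
                           rowMeans(mach$S_a[, trials, drop = FALSE]))
  f <- pmax(fs_$Fraw, 1 / fs_$Fraw)
  f[rowSums(abs(W)) == 0] <- NA_real_
  f
}

#' Bootstrap confidence volume of an ROI peak
#'
#' Resamples trials with replacement `n_boot` times; per replicate the
#' covariance, weights and F map are recomputed over the ROI and the peak
#' location recorded. The per-axis 95% extent is approximated as twice the
#' standard deviation of the bootstrapped peak coordinates.
#'
#' @param ds_filtered band-filtered `opm_trials`.
#' @param lf an `opm_leadfields`.
#' @param roi_mask logical vector over grid points (or ROI mask name).
#' @param n_boot bootstrap count (default 50).
#' @param seed RNG seed.
#' @param baseline_window,active_window contrast windows as in [f_map()].
#' @param regularization as in [lcmv_weights()].
#' @return an object of class `opm_confvol` with the bootstrap `peaks`
#'   (n_boot x 3 mm) and `extent` (2 x SD per axis, mm).
#' @export
confidence_volume <- function(ds_filtered, lf, roi_mask, n_boot = 50,
                              seed = 1L, baseline_window = c(-1, 0),
                              active_window = c(0, 1),
                              regularization = 0.05) {
  if (is.character(roi_mask)) roi_mask <- lf$grid$roi_masks[[roi_mask]]
  if (n_boot < 2) stop_opmlat("n_boot must be >= 2", "opmlat_config_error")
  pts <- which(roi_mask)
  if (length(pts) == 0L)
    stop_opmlat("ROI mask selects no grid points", "opmlat_config_error")
  mach <- bf_boot_machine(ds_filtered, lf, pts, baseline_window,
                          active_window, regularization)
  n_tr <- dim(ds_filtered$data)[3]
  set.seed(seed)
  peaks <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    f <- bf_boot_fstat(mach, sample.int(n_tr, n_tr, replace = TRUE))
    if (!any(is.finite(f)))
      stop_opmlat("no finite F value in ROI during bootstrap",
                  "opmlat_degenerate_error")
    ## deterministic near-tie rule: first point within 1e-9 relative of the
    ## maximum (exact ties arise in noise-free degenerate data)
    pk <- which(f >= max(f, na.rm = TRUE) * (1 - 1e-9))[1]
    peaks[b, ] <- lf$grid$points[pts[pk], ]
  }
  structure(list(peaks = peaks, extent = 2 * apply(peaks, 2, stats::sd),
                 n_boot = n_boot, seed = seed),
            class = "opm_confvol")
}

#' @export
print.opm_confvol <- function(x, ...) {
  cat(sprintf("<opm_confvol> %d bootstraps; 95%% extents (2 x SD): %.2f, %.2f, %.2f mm\n",
              x$n_boot, x$extent[1], x$extent[2], x$extent[3]))
  invisible(x)
}

#' Source-level time course at a grid point
#'
#' Applies the location-specific beamformer weights to the sensor data
#' (virtual channel), then reuses the sensor-level spectral chain: band
#' power, percent change from rest, and bootstrap SE over trials.
#'
#' @param ds an `opm_trials` (typically the preprocessed, broadband data).
#' @param w an `opm_bf_weights`.
#' @param point grid-point index.
#' @param band,rest_window,n_boot,seed spectral parameters, as in
#'   [bootstrap_sensor_course()].
#' @param half_bandwidth,window_s,step_s multitaper parameters.
#' @return an `opm_pct_course` with a single (virtual) channel.
#' @export
source_timecourse <- function(ds, w, point, band = c(15, 30),
                              rest_window = c(-2, 0), n_boot = 100,
                              seed = 1L, half_bandwidth = 1.5, window_s = 1,
                              step_s = 0.1) {
  if (point < 1 || point > nrow(w$W))
    stop_opmlat("point index outside the grid", "opmlat_config_error")
  si <- scalp_idx(ds$array)
  d <- dim(ds$data)
  Y <- matrix(ds$data[si, , ], length(si), d[2] * d[3])
  v <- array(as.numeric(w$W[point, ] %*% Y), dim = c(1, d[2], d[3]))
  vds <- structure(list(data = v, fs = ds$fs, time = ds$time,
                        array = sensor_array("virtual",
                                             matrix(w$grid$points[point, ], 1),
                                             matrix(c(0, 0, 1), 1), "scalp",
                                             ds$fs),
                        events = ds$events, stage = "virtual_channel",
                        provenance = ds$provenance),
                   class = "opm_trials")
  spec <- multitaper_tf(vds, fmin = max(1, band[1] - 5), fmax = band[2] + 5,
                        half_bandwidth = half_bandwidth, window_s = window_s,
                        step_s = step_s, channels = 1L)
  bootstrap_sensor_course(spec, band = band, rest_window = rest_window,
                          n_boot = n_boot, seed = seed)
}
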