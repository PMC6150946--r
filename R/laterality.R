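# Laterality-index curves: LI = (countL - countR) / (countL + countR) of
# supra-threshold voxels in homologous left/right ROIs, swept across
# statistical height thresholds, with bootstrap confidence intervals over
# trials. Positive LI means left lateralisation; counts use F >= threshold.

li_counts <- function(Fvals, roi_left, roi_right, thresholds) {
  cl <- vapply(thresholds, function(th) sum(Fvals[roi_left] >= th, na.rm = TRUE),
               integer(1))
  cr <- vapply(thresholds, function(th) sum(Fvals[roi_right] >= th, na.rm = TRUE),
               integer(1))
  tot <- cl + cr
  li <- ifelse(tot > 0, (cl - cr) / tot, NA_real_)
  data.frame(threshold = thresholds, count_left = cl, count_right = cr,
             LI = li, defined = tot > 0)
}

#' Laterality index across thresholds
#'
#' @param map an `opm_statmap`.
#' @param roi_left,roi_right logical masks over grid points (or mask names
#'   from the map's grid); must be disjoint.
#' @param thresholds ascending positive F thresholds; default 29 evenly
#'   spaced values on `[1, 15]`.
#' @return an object of class `opm_li_curve`; its `curve` data frame has
#'   `threshold, count_left, count_right, LI, defined` (LI is `NA`, never a
#'   silent 0, where both counts vanish).
#' @export
laterality_index <- function(map, roi_left = "IFG_left",
                             roi_right = "IFG_right",
                             thresholds = seq(1, 15, length.out = 29)) {
  if (is.character(roi_left)) roi_left <- map$grid$roi_masks[[roi_left]]
  if (is.character(roi_right)) roi_right <- map$grid$roi_masks[[roi_right]]
  if (is.null(roi_left) || is.null(roi_right))
    stop_opmlat("unknown ROI mask", "opmlat_config_error")
  if (any(roi_left & roi_right))
    stop_opmlat("left and right ROIs overlap", "opmlat_config_error")
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0))
    stop_opmlat("thresholds must be positive and ascending",
                "opmlat_config_error")
  curve <- li_counts(map$map$F, roi_left, roi_right, thresholds)
  structure(list(curve = curve, ci = NULL, n_boot = NULL, seed = NULL),
            class = "opm_li_curve")
}

#' @export
print.opm_li_curve <- function(x, ...) {
  def <- x$curve[x$curve$defined, ]
  cat(sprintf("<opm_li_curve> %d thresholds in [%g, %g]; LI range [%.2f, %.2f]%s\n",
              nrow(x$curve), min(x$curve$threshold), max(x$curve$threshold),
              if (nrow(def)) min(def$LI) else NA,
              if (nrow(def)) max(def$LI) else NA,
              if (!is.null(x$ci)) sprintf("; %d bootstraps", x$n_boot) else ""))
  invisible(x)
}

#' Bootstrap laterality-index curves
#'
#' Resamples trials with replacement; each replicate recomputes covariance,
#' beamformer weights, the ROI-restricted F map and the LI curve. Reported
#' CIs are 2.5/97.5 empirical percentiles over the replicates in which the
#' LI is defined; the fraction of undefined replicates is reported per
#' threshold rather than clamped.
#'
#' @param ds_filtered band-filtered `opm_trials`.
#' @param lf an `opm_leadfields`.
#' @param roi_left,roi_right logical masks over grid points (or names).
#' @param thresholds as in [laterality_index()].
#' @param n_boot bootstrap count (default 100).
#' @param seed RNG seed.
#' @param baseline_window,active_window contrast windows as in [f_map()].
#' @param regularization as in [lcmv_weights()].
#' @return an `opm_li_curve` whose `curve` carries the full-data point
#'   estimate and whose `ci` data frame has `ci_low, ci_high, n_defined`.
#' @export
bootstrap_li <- function(ds_filtered, lf, roi_left = "IFG_left",
                         roi_right = "IFG_right",
                         thresholds = seq(1, 15, length.out = 29),
                         n_boot = 100, seed = 1L,
                         baseline_window = c(-1, 0), active_window = c(0, 1),
                         regularization = 0.05) {
  if (n_boot < 2) stop_opmlat("n_boot must be >= 2", "opmlat_config_error")
  grid <- lf$grid
  if (is.character(roi_left)) roi_left <- grid$roi_masks[[roi_left]]
  if (is.character(roi_right)) roi_right <- grid$roi_masks[[roi_right]]
  if (any(roi_left & roi_right))
    stop_opmlat("left and right ROIs overlap", "opmlat_config_error")
  pts <- which(roi_left | roi_right)
  l_sub <- roi_left[pts]; r_sub <- roi_right[pts]
  mach <- bf_boot_machine(ds_filtered, lf, pts, baseline_window,
                          active_window, regularization)
  ## full-data point estimate
  n_tr <- dim(ds_filtered$data)[3]
  f_full <- bf_boot_fstat(mach, seq_len(n_tr))
  curve <- li_counts(f_full, l_sub, r_sub, thresholds)
  set.seed(seed)
  li_rep <- matrix(NA_real_, n_boot, length(thresholds))
  for (b in seq_len(n_boot)) {
    f <- bf_boot_fstat(mach, sample.int(n_tr, n_tr, replace = TRUE))
    li_rep[b, ] <- li_counts(f, l_sub, r_sub, thresholds)$LI
  }
  ci <- t(vapply(seq_along(thresholds), function(j) {
    v <- li_rep[!is.na(li_rep[, j]), j]
    if (length(v) == 0) c(NA_real_, NA_real_, 0)
    else c(stats::quantile(v, 0.025, names = FALSE),
           stats::quantile(v, 0.975, names = FALSE), length(v))
  }, numeric(3)))
  structure(list(curve = curve,
                 ci = data.frame(threshold = thresholds, ci_low = ci[, 1],
                                 ci_high = ci[, 2], n_defined = ci[, 3]),
                 replicates = li_rep, n_boot = n_boot, seed = seed),
            class = "opm_li_curve")
}

#' Export a laterality curve as TSV
#'
#' Columns: `threshold, count_left, count_right, LI, ci_low, ci_high,
#' n_defined` (CI columns `NA` when the curve was not bootstrapped).
#' @param li an `opm_li_curve`.
#' @param path output TSV.
#' @export
write_li_curve <- function(li, path) {
  df <- li$curve
  if (!is.null(li$ci)) {
    df$ci_low <- li$ci$ci_low
    df$ci_high <- li$ci$ci_high
    df$n_defined <- li$ci$n_defined
  } else {
    df$ci_low <- NA; df$ci_high <- NA; df$n_defined <- NA
  }
  df$defined <- NULL
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
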