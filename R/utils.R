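# Condition helpers and provenance plumbing shared across the pipeline.

stop_opmlat <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "opmlat_error")))
}

warn_opmlat <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "opmlat_warning")))
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

## A provenance record is a named list; every dataset-mutating operation
## appends one so a processed file can be traced back to its inputs.
## Deliberately timestamp-free: equal seeds must yield identical containers
## (wall-clock timing belongs to run.log, not the data provenance).
prov_record <- function(op, params = list()) {
  list(op = op, params = params)
}

append_prov <- function(ds, op, params = list()) {
  ds$provenance <- c(ds$provenance, list(prov_record(op, params)))
  ds
}

## Closest index on a sorted axis; used for window selection.
axis_window_idx <- function(axis, window, what = "window") {
  if (length(window) != 2L || window[2] < window[1])
    stop_opmlat(sprintf("%s must be an increasing length-2 interval", what),
                "opmlat_config_error")
  idx <- which(axis >= window[1] - 1e-9 & axis <= window[2] + 1e-9)
  if (length(idx) == 0L)
    stop_opmlat(sprintf("%s [%g, %g] contains no axis samples", what,
                        window[1], window[2]), "opmlat_config_error")
  idx
}
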