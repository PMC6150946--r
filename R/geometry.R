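# Sensor-array and source-grid geometry. Everything lives in one MNI-aligned
# head frame in millimetres: sensor positions/orientations, the conductor
# sphere standing in for the inner-skull surface, grid points and ROI masks.

#' Construct a sensor array
#'
#' A sensor array holds the positions (mm, MNI-aligned head frame), radial
#' sensing orientations (unit vectors) and roles (`"scalp"` or `"reference"`)
#' of a set of magnetometer channels.
#'
#' @param labels character vector of channel identifiers.
#' @param positions numeric matrix, channels x 3, in millimetres.
#' @param orientations numeric matrix, channels x 3; each row must have unit
#'   norm (renormalized if within `1e-6`, rejected otherwise).
#' @param role character vector, `"scalp"` or `"reference"` per channel.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `opm_sensor_array`.
#' @export
sensor_array <- function(labels, positions, orientations, role,
                         sampling_rate = 1000) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  n <- length(labels)
  if (nrow(positions) != n || nrow(orientations) != n || length(role) != n)
    stop_opmlat("labels, positions, orientations and role must agree in length",
                "opmlat_format_error")
  if (ncol(positions) != 3L || ncol(orientations) != 3L)
    stop_opmlat("positions and orientations must have 3 columns",
                "opmlat_format_error")
  if (!all(role %in% c("scalp", "reference")))
    stop_opmlat("role must be 'scalp' or 'reference'", "opmlat_format_error")
  nrm <- sqrt(rowSums(orientations^2))
  bad <- abs(nrm - 1) > 1e-6
  if (any(bad))
    stop_opmlat(sprintf("non-unit orientation (norm %.6g) for channel(s) %s",
                        nrm[which(bad)[1]],
                        paste(labels[bad], collapse = ", ")),
                "opmlat_validation_error")
  orientations <- orientations / nrm
  structure(list(labels = as.character(labels),
                 positions = positions,
                 orientations = orientations,
                 role = role,
                 sampling_rate = sampling_rate),
            class = "opm_sensor_array")
}

#' @export
print.opm_sensor_array <- function(x, ...) {
  cat(sprintf("<opm_sensor_array> %d channels (%d scalp, %d reference), %g Hz\n",
              length(x$labels), sum(x$role == "scalp"),
              sum(x$role == "reference"), x$sampling_rate))
  invisible(x)
}

scalp_idx <- function(array) which(array$role == "scalp")
ref_idx <- function(array) which(array$role == "reference")

#' Read a sensor array from TSV or JSON
#'
#' The TSV schema has one row per channel with columns
#' `label, x_mm, y_mm, z_mm, ox, oy, oz, role`; the JSON format mirrors the
#' same fields as an array of records plus a top-level `sampling_rate`.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"json"`; inferred from the file extension when
#'   missing.
#' @param sampling_rate Hz; used for TSV input (JSON carries its own).
#' @return an `opm_sensor_array`.
#' @export
load_sensor_array <- function(path, format = NULL, sampling_rate = 1000) {
  if (!file.exists(path))
    stop_opmlat(sprintf("no such file: %s", path), "opmlat_io_error")
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  cols <- c("label", "x_mm", "y_mm", "z_mm", "ox", "oy", "oz", "role")
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$channels, stringsAsFactors = FALSE)
    sampling_rate <- obj$sampling_rate %||% sampling_rate
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop_opmlat(sprintf("sensor table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "opmlat_format_error")
  sensor_array(df$label,
               cbind(df$x_mm, df$y_mm, df$z_mm),
               cbind(df$ox, df$oy, df$oz),
               df$role, sampling_rate = sampling_rate)
}

#' Write a sensor array to TSV or JSON
#'
#' @param array an `opm_sensor_array`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`; inferred from the extension when missing.
#' @export
write_sensor_array <- function(array, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  df <- data.frame(label = array$labels,
                   x_mm = array$positions[, 1], y_mm = array$positions[, 2],
                   z_mm = array$positions[, 3],
                   ox = array$orientations[, 1], oy = array$orientations[, 2],
                   oz = array$orientations[, 3],
                   role = array$role, stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(sampling_rate = array$sampling_rate,
                              channels = df),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Default bilateral frontotemporal helmet
#'
#' Places `n_scalp` radial magnetometers quasi-uniformly over the lateral
#' frontotemporal scalp of both hemispheres at scalp radius
#' `scalp_radius` + `standoff` (the sensitive cell of an OPM sits ~6.5 mm
#' above the scalp), plus `n_ref` reference magnetometers ~30 cm behind the
#' head. No published coordinates exist for this layout, so it is a
#' synthetic stand-in, parameterized rather than hard-coded.
#'
#' @param n_scalp number of scalp channels (split across hemispheres).
#' @param n_ref number of reference channels.
#' @param center head-sphere centre (mm).
#' @param scalp_radius scalp-sphere radius (mm).
#' @param standoff radial sensor offset above the scalp (mm).
#' @param sampling_rate Hz.
#' @return an `opm_sensor_array`.
#' @export
default_helmet <- function(n_scalp = 26, n_ref = 4,
                           center = c(0, 0, 40), scalp_radius = 90,
                           standoff = 6.5, sampling_rate = 1000) {
  n_left <- ceiling(n_scalp / 2)
  n_right <- n_scalp - n_left
  patch <- function(n, side) {
    # golden-angle spiral over a frontotemporal patch:
    # azimuth 35..145 deg from +y toward +/-x, elevation -5..55 deg
    i <- seq_len(n) - 0.5
    az <- (35 + 110 * ((i * 0.61803398875) %% 1)) * pi / 180
    el <- (-5 + 60 * i / n) * pi / 180
    sgn <- if (side == "left") -1 else 1
    dir <- cbind(sgn * cos(el) * sin(az), cos(el) * cos(az), sin(el))
    dir / sqrt(rowSums(dir^2))
  }
  dirs <- rbind(patch(n_left, "left"), patch(n_right, "right"))
  r <- scalp_radius + standoff
  pos <- sweep(dirs * r, 2, center, "+")
  lab <- sprintf("S%02d", seq_len(n_scalp))
  ref_pos <- cbind(seq(-60, 60, length.out = n_ref), -300 + abs(seq(-15, 15, length.out = n_ref)), 60)
  ref_ori <- matrix(rep(c(0, 1, 0), n_ref), ncol = 3, byrow = TRUE)
  sensor_array(c(lab, sprintf("REF%d", seq_len(n_ref))),
               rbind(pos, ref_pos),
               rbind(dirs, ref_ori),
               c(rep("scalp", n_scalp), rep("reference", n_ref)),
               sampling_rate = sampling_rate)
}

#' Fit the conductor sphere to scalp sensor positions
#'
#' Least-squares sphere through the scalp positions (algebraic Kasa fit,
#' which is exact when the points lie on a true sphere), with the radius
#' shrunk by a scalp-to-inner-skull margin to stand in for the inner-skull
#' boundary used by single-shell forward models.
#'
#' @param scalp_positions numeric matrix, n x 3 (mm); n >= 4, non-coplanar.
#' @param margin radius shrinkage in mm (default 15).
#' @return an object of class `opm_sphere` with fields `center`, `radius`
#'   (mm) and the fit RMS residual `rms` (of the unshrunk sphere).
#' @export
fit_conductor_sphere <- function(scalp_positions, margin = 15) {
  P <- as.matrix(scalp_positions)
  if (nrow(P) < 4)
    stop_opmlat("need at least 4 points to fit a sphere", "opmlat_fit_error")
  # |p|^2 = 2 c.p + (r^2 - |c|^2): linear in (c, d)
  A <- cbind(2 * P, 1)
  y <- rowSums(P^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4)
    stop_opmlat("degenerate (coplanar or coincident) points: sphere fit is ill-posed",
                "opmlat_fit_error")
  beta <- qr.coef(qr_A, y)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (r2 <= 0)
    stop_opmlat("sphere fit produced non-positive radius", "opmlat_fit_error")
  radius <- sqrt(r2)
  resid <- sqrt(rowSums(sweep(P, 2, center)^2)) - radius
  if (radius - margin <= 0)
    stop_opmlat("margin exceeds fitted radius", "opmlat_fit_error")
  structure(list(center = unname(center), radius = radius - margin,
                 scalp_radius = radius, margin = margin,
                 rms = sqrt(mean(resid^2))),
            class = "opm_sphere")
}

#' @export
print.opm_sphere <- function(x, ...) {
  cat(sprintf("<opm_sphere> center (%.1f, %.1f, %.1f) mm, radius %.1f mm (fit RMS %.2g mm)\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms))
  invisible(x)
}

#' Build a volumetric source grid inside the conductor sphere
#'
#' Regular cubic lattice clipped to points whose distance to the sphere
#' centre is at most `radius - margin`. Hemisphere labels follow the sign of
#' the MNI x coordinate (midline band `|x| < eps`). ROI masks are balls
#' around named centres; a spec of the form `list(IFG = list(center = c(-53, 17, 19),
#' radius = 20, mirror = TRUE))` produces masks `IFG_left` and `IFG_right`
#' (the mirrored ball negates x).
#'
#' @param sphere an `opm_sphere`.
#' @param spacing lattice spacing in mm (> 0).
#' @param roi_specs named list of `list(center, radius, mirror = TRUE)` specs.
#' @param margin inner margin to the sphere surface in mm (default 10).
#' @param hemi_eps half-width of the excluded midline band in mm.
#' @return an object of class `opm_grid` with fields `points` (n x 3 mm),
#'   `spacing`, `hemisphere` and `roi_masks`.
#' @export
build_source_grid <- function(sphere, spacing = 5, roi_specs = list(),
                              margin = 10, hemi_eps = 0.5) {
  if (spacing <= 0)
    stop_opmlat("spacing must be positive", "opmlat_config_error")
  rmax <- sphere$radius - margin
  if (rmax <= 0)
    stop_opmlat("margin leaves no interior volume", "opmlat_config_error")
  ax <- function(c0) {
    k <- floor(rmax / spacing)
    c0 + spacing * (-k:k)
  }
  pts <- as.matrix(expand.grid(x = ax(sphere$center[1]),
                               y = ax(sphere$center[2]),
                               z = ax(sphere$center[3])))
  dimnames(pts) <- NULL
  keep <- sqrt(rowSums(sweep(pts, 2, sphere$center)^2)) <= rmax + 1e-9
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop_opmlat(sprintf("no grid points: spacing %g mm too coarse for interior radius %g mm",
                        spacing, rmax), "opmlat_config_error")
  hemi <- ifelse(pts[, 1] < -hemi_eps, "left",
                 ifelse(pts[, 1] > hemi_eps, "right", "midline"))
  masks <- list()
  for (nm in names(roi_specs)) {
    spec <- roi_specs[[nm]]
    ctr <- spec$center
    if (sqrt(sum((ctr - sphere$center)^2)) >= sphere$radius)
      stop_opmlat(sprintf("ROI '%s' centre lies outside the conductor sphere", nm),
                  "opmlat_config_error")
    ball <- function(c3) sqrt(rowSums(sweep(pts, 2, c3)^2)) <= spec$radius + 1e-9
    if (isTRUE(spec$mirror %||% TRUE)) {
      masks[[paste0(nm, "_left")]] <- ball(ctr * c(ifelse(ctr[1] <= 0, 1, -1), 1, 1))
      masks[[paste0(nm, "_right")]] <- ball(ctr * c(ifelse(ctr[1] <= 0, -1, 1), 1, 1))
    } else {
      masks[[nm]] <- ball(ctr)
    }
  }
  structure(list(points = pts, spacing = spacing, hemisphere = hemi,
                 roi_masks = masks, sphere = sphere),
            class = "opm_grid")
}

#' @export
print.opm_grid <- function(x, ...) {
  cat(sprintf("<opm_grid> %d points at %g mm spacing (%d left / %d right), masks: %s\n",
              nrow(x$points), x$spacing, sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"),
              if (length(x$roi_masks)) paste(names(x$roi_masks), collapse = ", ") else "none"))
  invisible(x)
}

#' Serialize / load a source grid as JSON
#'
#' @param grid an `opm_grid`.
#' @param path JSON file.
#' @export
write_source_grid <- function(grid, path) {
  jsonlite::write_json(list(schema = "opmlat-grid-1",
                            spacing = grid$spacing,
                            sphere = list(center = grid$sphere$center,
                                          radius = grid$sphere$radius),
                            points = grid$points,
                            hemisphere = grid$hemisphere,
                            roi_masks = lapply(grid$roi_masks, which)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_source_grid
#' @export
read_source_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "opmlat-grid-1"))
    stop_opmlat(sprintf("unsupported grid schema '%s'", obj$schema %||% "<none>"),
                "opmlat_schema_error")
  n <- nrow(obj$points)
  masks <- lapply(obj$roi_masks, function(ix) {
    m <- rep(FALSE, n); m[ix] <- TRUE; m
  })
  sph <- structure(list(center = obj$sphere$center, radius = obj$sphere$radius,
                        rms = NA_real_), class = "opm_sphere")
  structure(list(points = obj$points, spacing = obj$spacing,
                 hemisphere = obj$hemisphere, roi_masks = masks, sphere = sph),
            class = "opm_grid")
}
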