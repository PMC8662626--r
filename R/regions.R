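#' Extract one region's binary mask
#'
#' Mask is `TRUE` exactly where the volume carries the requested label. A
#' label absent from the volume yields an empty mask with a warning (the
#' downstream dimension fit then raises an empty-ROI error).
#'
#' @param volume a [LabelVolume-class].
#' @param label region label in 1..40.
#' @return 3D logical array of the volume's shape.
#' @seealso [wholeBrainMask()], [measureSession()]
#' @export
extractRegion <- function(volume, label) {
  stopifnot(is(volume, "LabelVolume"))
  label <- as.integer(label)
  if (is.na(label) || label < 1L || label > 40L)
    stop("label must lie in 1..40", call. = FALSE)
  mask <- volume@data == label
  if (!any(mask))
    warning("label ", label, " not present in volume; empty mask",
            call. = FALSE)
  mask
}

#' Union mask of all segmented structures
#'
#' `TRUE` wherever the label is positive: the whole segmented brain, the ROI
#' used for whole-volume dimension estimates.
#'
#' @param volume a [LabelVolume-class].
#' @return 3D logical array.
#' @export
wholeBrainMask <- function(volume) {
  stopifnot(is(volume, "LabelVolume"))
  volume@data > 0L
}

#' Measure volume and fractal dimension per region for one session
#'
#' For each requested label, and for the whole segmented volume, computes
#' the voxel count, the physical volume (voxel count times the voxel volume
#' in mm^3) and the box-counting dimension fit. Regions absent from the
#' volume get voxel count 0 and `NA` dimension columns. Scales are in voxel
#' units; the dimension is dimensionless, so physical spacing does not enter
#' the fit, but anisotropic spacing draws a warning since the voxel grid
#' then distorts physical shape.
#'
#' @param volume a [LabelVolume-class].
#' @param session a one-row session record (as from [parseSessionId()]), or
#'   `NULL` for anonymous measurements.
#' @param labels integer vector of region labels to measure.
#' @param schedule a [ScaleSchedule-class].
#' @param labelMap named integer vector used to attach region names.
#' @return a `data.frame` with one row per region plus a `whole_volume` row:
#'   columns `session_id`, `subject_id`, `day`, `region_label`,
#'   `region_name`, `voxel_count`, `volume_mm3`, `fd`, `rmse`, `r2`,
#'   `n_points`.
#' @export
measureSession <- function(volume, session = NULL, labels,
                           schedule = scaleSchedule(),
                           labelMap = defaultLabelMap()) {
  stopifnot(is(volume, "LabelVolume"))
  labels <- as.integer(labels)
  if (length(labels) == 0L)
    stop("labels must be nonempty", call. = FALSE)
  if (length(unique(volume@spacing)) > 1L)
    warning("anisotropic voxel spacing (", paste(volume@spacing,
            collapse = " x "), " mm): box counting is done on the voxel ",
            "grid", call. = FALSE)
  if (is.null(session))
    session <- data.frame(subject_id = NA_character_,
                          session_id = NA_character_, day = NA_integer_)
  voxVol <- prod(volume@spacing)
  oneRegion <- function(mask, label, name) {
    vc <- sum(mask)
    if (vc > 0L) {
      est <- estimateFD(mask, schedule)
      data.frame(session_id = session$session_id,
                 subject_id = session$subject_id, day = session$day,
                 region_label = label, region_name = name,
                 voxel_count = vc, volume_mm3 = vc * voxVol,
                 fd = est@fd, rmse = est@rmse, r2 = est@r2,
                 n_points = est@nPoints, stringsAsFactors = FALSE)
    } else {
      data.frame(session_id = session$session_id,
                 subject_id = session$subject_id, day = session$day,
                 region_label = label, region_name = name,
                 voxel_count = 0L, volume_mm3 = 0,
                 fd = NA_real_, rmse = NA_real_, r2 = NA_real_,
                 n_points = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  rows <- list(oneRegion(wholeBrainMask(volume), NA_integer_,
                         "whole_volume"))
  for (lab in labels) {
    name <- names(labelMap)[match(lab, labelMap)]
    if (is.na(name) || is.null(name)) name <- paste0("label_", lab)
    mask <- suppressWarnings(extractRegion(volume, lab))
    rows[[length(rows) + 1L]] <- oneRegion(mask, lab, name)
  }
  do.call(rbind, rows)
}

#' Multi-session comparison table
#'
#' Pivots per-region measurements of several sessions into a wide table
#' (rows = sessions sorted by day, columns = regions, cells = fitted
#' dimension) and computes the per-region relative variation
#' `(max - min) / mean * 100` (percent) across sessions -- the repeat-scan
#' stability summary. All sessions must carry the same region set.
#'
#' @param measures rows from [measureSession()] over one or more sessions.
#' @param statistic variation statistic; only `"range_over_mean"` is built
#'   in, but a function `(values) -> percent` may be supplied.
#' @return a list of class `fdComparison`: `$fd` the wide session-by-region
#'   data frame, `$variation` named percent variation per region (`NA` with
#'   a single session).
#' @export
compareSessions <- function(measures, statistic = "range_over_mean") {
  stopifnot(is.data.frame(measures))
  bySession <- split(measures, measures$session_id)
  regionSets <- lapply(bySession, function(m)
    sort(paste(m$region_name)))
  if (length(unique(regionSets)) != 1L)
    stop("sessions carry different region sets; cannot compare",
         call. = FALSE)
  days <- vapply(bySession, function(m) m$day[1L], numeric(1))
  bySession <- bySession[order(days)]
  regions <- bySession[[1L]]$region_name
  wide <- data.frame(session_id = names(bySession),
                     day = sort(days), stringsAsFactors = FALSE)
  for (r in regions)
    wide[[r]] <- vapply(bySession, function(m)
      m$fd[match(r, m$region_name)], numeric(1))
  statFun <- if (is.function(statistic)) statistic
    else switch(statistic,
      range_over_mean = function(v) (max(v) - min(v)) / mean(v) * 100,
      stop("unknown variation statistic: ", statistic, call. = FALSE))
  variation <- if (length(bySession) < 2L)
    stats::setNames(rep(NA_real_, length(regions)), regions)
  else vapply(regions, function(r) {
    v <- wide[[r]]
    if (anyNA(v)) NA_real_ else statFun(v)
  }, numeric(1))
  structure(list(fd = wide, variation = variation),
            class = "fdComparison")
}

#' @export
print.fdComparison <- function(x, ...) {
  cat("Per-region FD across", nrow(x$fd), "sessions\n")
  print(x$fd, ...)
  cat("\nRelative variation (max-min)/mean, percent:\n")
  print(round(x$variation, 3), ...)
  invisible(x)
}
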