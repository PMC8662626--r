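#' Generate the logarithmic box-edge schedule
#'
#' Box edge lengths are spaced evenly in log10:
#' \deqn{s_k = 10^{\,minExp + k\,(maxExp - minExp)/(nPoints-1)}, \quad
#'       k = 0, \dots, nPoints-1.}
#' The defaults (20 points, exponents 0.01 to 0.9505, i.e. a constant log10
#' step of 0.0495) are the schedule the method was calibrated with: twenty
#' points balance fit stability against counting cost, and the edges span
#' roughly 1.02 to 8.92 voxels. Alternatively an explicit vector of edge
#' lengths may be supplied via `scales`.
#'
#' @param nPoints number of scales (>= 2).
#' @param minExp,maxExp log10 of the smallest/largest box edge;
#'   `maxExp > minExp >= 0` and the resulting edges must all exceed 1 voxel.
#' @param scales optional explicit strictly increasing vector of edge
#'   lengths (> 1); overrides the other arguments.
#' @return a [ScaleSchedule-class].
#' @examples
#' sched <- scaleSchedule()
#' head(scales(sched))
#' head(epsilons(sched))
#' @export
scaleSchedule <- function(nPoints = 20L, minExp = 0.01, maxExp = 0.9505,
                          scales = NULL) {
  if (!is.null(scales))
    return(new("ScaleSchedule", scales = as.numeric(scales)))
  nPoints <- as.integer(nPoints)
  if (is.na(nPoints) || nPoints < 2L)
    stop("nPoints must be an integer >= 2", call. = FALSE)
  if (!is.finite(minExp) || !is.finite(maxExp) || maxExp <= minExp ||
      minExp < 0)
    stop("need maxExp > minExp >= 0", call. = FALSE)
  step <- (maxExp - minExp) / (nPoints - 1L)
  s <- 10^(minExp + (seq_len(nPoints) - 1L) * step)
  new("ScaleSchedule", scales = s)
}

#' @rdname accessors
#' @export
setMethod("scales", "ScaleSchedule", function(x) x@scales)

#' @rdname accessors
#' @export
setMethod("epsilons", "ScaleSchedule", function(x) 1 / x@scales)

#' @describeIn scaleSchedule number of scales in the schedule.
#' @param x a `ScaleSchedule`.
#' @export
setMethod("length", "ScaleSchedule", function(x) length(x@scales))

setMethod("show", "ScaleSchedule", function(object) {
  s <- object@scales
  cat("ScaleSchedule with ", length(s), " box edge lengths in [",
      format(s[1]), ", ", format(s[length(s)]), "] voxels\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("scales", "BoxCountSeries", function(x) x@schedule@scales)

#' @rdname accessors
#' @export
setMethod("counts", "BoxCountSeries", function(x) x@counts)

setMethod("show", "BoxCountSeries", function(object) {
  cat("BoxCountSeries: ", length(object@counts), " (scale, N) pairs, N in [",
      min(object@counts), ", ", max(object@counts), "]\n", sep = "")
})

#' @describeIn fitFD the (scale, N) series as a two-column data frame
#'   (columns `scale`, `n_boxes`), the layout used for series export.
#' @param x a `BoxCountSeries`.
#' @param row.names,optional,... passed per the generic; unused.
#' @export
as.data.frame.BoxCountSeries <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(scale = x@schedule@scales, n_boxes = x@counts)
}

.asMask <- function(mask) {
  if (is(mask, "LabelVolume")) mask <- mask@data
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  mask != 0
}

#' Count occupied boxes at one edge length
#'
#' Divides the voxel grid into cubic cells of edge `s` (voxel units),
#' anchored at the array index origin, and counts the distinct cells that
#' contain at least one foreground voxel: voxel \eqn{(i,j,k)} (zero-based)
#' belongs to cell \eqn{(\lfloor i/s\rfloor, \lfloor j/s\rfloor, \lfloor
#' k/s\rfloor)}. Non-integer edges are supported; this is the plain
#' single-lattice counting scheme, with no overlapping or offset-averaged
#' grids.
#'
#' Edges \eqn{s \le 1} are rejected rather than clamped: every occupied
#' voxel would occupy its own cell, pinning the count at the voxel count and
#' flattening the log-log fit.
#'
#' @param mask 3D logical/numeric array (nonzero = foreground), or a
#'   [LabelVolume-class] whose nonzero voxels are counted.
#' @param s box edge length in voxels, > 1.
#' @return the number of occupied cells (a positive integer).
#' @examples
#' cube <- array(TRUE, c(8, 8, 8))
#' countBoxes(cube, 2)  # 4^3 = 64
#' @export
countBoxes <- function(mask, s) {
  mask <- .asMask(mask)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 1)
    stop("box edge length s must be a single finite number > 1",
         call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  cells <- floor((idx - 1L) / s)
  K <- floor((dim(mask) - 1L) / s) + 1
  key <- cells[, 1L] + K[1L] * (cells[, 2L] + K[2L] * cells[, 3L])
  length(unique(key))
}

#' Fit the box-counting dimension from a count series
#'
#' Ordinary least squares of \eqn{\log_{10} N_k} on \eqn{\log_{10} s_k}; the
#' dimension estimate is the negated slope (the log base cancels in the
#' slope). The residual root-mean-square, in \eqn{\log_{10} N} units, is
#' reported as the linearity diagnostic, and \eqn{R^2} is defined as 0 when
#' the response has zero variance (e.g. constant counts, slope 0, dimension
#' 0).
#'
#' @param series a [BoxCountSeries-class] with at least 2 points.
#' @return an [FDResult-class].
#' @examples
#' sched <- scaleSchedule()
#' n <- round(10^(5 - 3 * log10(scales(sched))))
#' fit <- fitFD(new("BoxCountSeries", schedule = sched, counts = n))
#' fd(fit)
#' @export
fitFD <- function(series) {
  stopifnot(is(series, "BoxCountSeries"))
  x <- log10(series@schedule@scales)
  y <- log10(series@counts)
  if (any(series@counts <= 0))
    stop("all counts must be positive to take logs", call. = FALSE)
  if (length(unique(x)) < 2L || length(x) < 2L)
    stop("need at least 2 distinct scales to fit", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) max(0, 1 - sum(res^2) / ssTot) else 0
  slope <- unname(fit$coefficients[2L])
  new("FDResult",
      fd = -slope, slope = slope,
      intercept = unname(fit$coefficients[1L]),
      rmse = sqrt(mean(res^2)), r2 = min(r2, 1),
      nPoints = length(y), series = series)
}

#' Estimate the box-counting fractal dimension of a mask
#'
#' Counts occupied boxes at every edge length of the schedule
#' ([countBoxes()]) and fits the log-log line ([fitFD()]). The series stored
#' in the result is exactly the counted series.
#'
#' @param mask 3D array (nonzero = foreground) or [LabelVolume-class].
#' @param schedule a [ScaleSchedule-class]; default [scaleSchedule()].
#' @return an [FDResult-class].
#' @examples
#' fit <- estimateFD(array(TRUE, c(32, 32, 1)))
#' fd(fit)   # near 2: a plane
#' rmse(fit)
#' @export
estimateFD <- function(mask, schedule = scaleSchedule()) {
  stopifnot(is(schedule, "ScaleSchedule"))
  mask <- .asMask(mask)
  n <- vapply(schedule@scales, function(s) countBoxes(mask, s), numeric(1))
  fitFD(new("BoxCountSeries", schedule = schedule, counts = n))
}

#' Linearity flag from the fit diagnostic
#'
#' A box-counting dimension only summarises the structure when the log-log
#' relation is close to linear. This report-only gate compares the fit RMSE
#' with a threshold (default 0.05 log10 units): above it, the structure is
#' flagged as a candidate for multifractal analysis, which is outside this
#' package's scope -- the flag is informational and never aborts a pipeline.
#'
#' @param result an [FDResult-class].
#' @param rmseThreshold positive RMSE threshold in log10 N units.
#' @return `"fractal_ok"` or `"multifractal_suspect"`.
#' @export
linearityFlag <- function(result, rmseThreshold = 0.05) {
  stopifnot(is(result, "FDResult"))
  if (!is.numeric(rmseThreshold) || rmseThreshold <= 0)
    stop("rmseThreshold must be > 0", call. = FALSE)
  if (result@rmse <= rmseThreshold) "fractal_ok" else "multifractal_suspect"
}

#' @rdname accessors
#' @export
setMethod("fd", "FDResult", function(x) x@fd)

#' @rdname accessors
#' @export
setMethod("fdSlope", "FDResult", function(x) x@slope)

#' @rdname accessors
#' @export
setMethod("fdIntercept", "FDResult", function(x) x@intercept)

#' @rdname accessors
#' @export
setMethod("rmse", "FDResult", function(x) x@rmse)

#' @rdname accessors
#' @export
setMethod("rsquared", "FDResult", function(x) x@r2)

#' @rdname accessors
#' @export
setMethod("nPoints", "FDResult", function(x) x@nPoints)

#' @rdname accessors
#' @export
setMethod("countSeries", "FDResult", function(x) x@series)

setMethod("show", "FDResult", function(object) {
  cat(sprintf(
    "FDResult: fd = %.6f (rmse %.4f, r2 %.4f, %d points) [%s]\n",
    object@fd, object@rmse, object@r2, object@nPoints,
    linearityFlag(object)))
})

#' Serialize an FD fit
#'
#' `fdResultRow()` flattens an [FDResult-class] into a one-row data frame
#' (columns `fd`, `slope`, `intercept`, `rmse`, `r2`, `n_points` plus any
#' identifying columns passed in `...`), the layout used for CSV reports.
#' `fdResultJSON()` returns the same fields plus the full (scale, N) series
#' as a JSON string.
#'
#' @param result an [FDResult-class].
#' @param ... named length-1 identifying fields (e.g. `session_id`,
#'   `region`) prepended to the row.
#' @return a one-row `data.frame`, or a JSON string.
#' @export
fdResultRow <- function(result, ...) {
  stopifnot(is(result, "FDResult"))
  ids <- list(...)
  cbind(if (length(ids)) as.data.frame(ids, stringsAsFactors = FALSE),
        data.frame(fd = result@fd, slope = result@slope,
                   intercept = result@intercept, rmse = result@rmse,
                   r2 = result@r2, n_points = result@nPoints))
}

#' @rdname fdResultRow
#' @export
fdResultJSON <- function(result, ...) {
  stopifnot(is(result, "FDResult"))
  jsonlite::toJSON(c(list(...),
                     list(fd = result@fd, slope = result@slope,
                          intercept = result@intercept, rmse = result@rmse,
                          r2 = result@r2, n_points = result@nPoints,
                          scale = result@series@schedule@scales,
                          n_boxes = result@series@counts)),
                   auto_unbox = TRUE, digits = NA)
}
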