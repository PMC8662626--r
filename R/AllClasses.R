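#' @import methods
NULL

#' LabelVolume: a segmented 3D label image
#'
#' Container for a three-dimensional integer label array together with its
#' per-axis voxel size in millimetres. Voxel value 0 is background; positive
#' values identify segmented structures. Volumes produced by the segmentation
#' stage consumed here carry labels in 0--40 (see [defaultLabelMap()] for the
#' named subset), but any non-negative integer labelling is accepted by the
#' container itself; conformance to the 0--40 convention can be asserted with
#' [checkLabelConformance()].
#'
#' @slot data 3D integer array of region labels.
#' @slot spacing numeric(3), strictly positive voxel edge lengths in mm.
#'
#' @seealso [labelVolume()], [readLabelVolume()], [extractRegion()]
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!(is.integer(object@data) || is.logical(object@data)))
      msg <- c(msg, "data must be stored as integer")
    if (length(object@data) && min(object@data, na.rm = TRUE) < 0L)
      msg <- c(msg, "labels must be >= 0 (0 is background)")
    if (anyNA(object@data))
      msg <- c(msg, "labels must not contain NA")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three strictly positive numbers")
    if (length(msg)) msg else TRUE
  }
)

#' ScaleSchedule: ordered box edge lengths for box counting
#'
#' The ordered box edge lengths \eqn{s} (in voxel units) at which boxes are
#' counted. The scaling factor of the box-counting limit is
#' \eqn{\epsilon = 1/s}. All edges must exceed 1 voxel: at \eqn{s \le 1}
#' every occupied voxel is its own box and the log--log fit degenerates.
#'
#' @slot scales strictly increasing numeric vector of box edge lengths, all
#'   greater than 1, length at least 2.
#'
#' @seealso [scaleSchedule()], [countBoxes()], [estimateFD()]
#' @export
setClass("ScaleSchedule",
  representation(scales = "numeric"),
  validity = function(object) {
    s <- object@scales
    msg <- character()
    if (length(s) < 2L)
      msg <- c(msg, "need at least 2 scales")
    if (!all(is.finite(s)) || any(s <= 1))
      msg <- c(msg, "every scale must be a finite number > 1")
    if (is.unsorted(s, strictly = TRUE))
      msg <- c(msg, "scales must be strictly increasing")
    if (length(msg)) msg else TRUE
  }
)

#' BoxCountSeries: occupied-box counts along a scale schedule
#'
#' Pairs \eqn{(s_k, N_k)} of box edge length and occupied-box count for one
#' mask. Counts from [countBoxes()] are positive integers (at least 1 for a
#' nonempty mask); the container also admits real-valued series, e.g. exact
#' power laws used to validate the fit. Note
#' that for an origin-anchored grid at non-integer \eqn{s}, \eqn{N(s)} is
#' typically but not always non-increasing in \eqn{s}: sparse masks can
#' straddle more cell boundaries at a coarser misaligned grid, so
#' monotonicity is a property of well-filled masks, not a container
#' invariant.
#'
#' @slot schedule a [ScaleSchedule-class].
#' @slot counts numeric vector of positive integer-valued counts, one per
#'   scale.
#'
#' @seealso [estimateFD()], [fitFD()]
#' @export
setClass("BoxCountSeries",
  representation(schedule = "ScaleSchedule", counts = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) != length(object@schedule@scales))
      msg <- c(msg, "one count per scale required")
    if (!all(is.finite(object@counts)) || any(object@counts < 1))
      msg <- c(msg, "counts must be >= 1 (nonempty mask)")
    if (length(msg)) msg else TRUE
  }
)

#' FDResult: a fitted box-counting dimension
#'
#' Result of the ordinary least-squares fit of \eqn{\log_{10} N_k} on
#' \eqn{\log_{10} s_k}. The fractal dimension estimate is the negated slope.
#' The root-mean-square residual (in \eqn{\log_{10} N} units) is the
#' linearity diagnostic: a large value means a single dimension does not
#' describe the structure well (see [linearityFlag()]).
#'
#' @slot fd fractal dimension estimate (dimensionless), equal to `-slope`.
#' @slot slope fitted slope of log10 N on log10 s.
#' @slot intercept fitted intercept.
#' @slot rmse root-mean-square residual, log10 N units.
#' @slot r2 coefficient of determination in [0, 1]; defined as 0 for a
#'   zero-variance response.
#' @slot nPoints number of (scale, count) points used.
#' @slot series the [BoxCountSeries-class] the fit was computed from.
#'
#' @seealso [fitFD()], [estimateFD()], [linearityFlag()]
#' @export
setClass("FDResult",
  representation(fd = "numeric", slope = "numeric", intercept = "numeric",
                 rmse = "numeric", r2 = "numeric", nPoints = "integer",
                 series = "BoxCountSeries"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@fd, -object@slope)))
      msg <- c(msg, "fd must equal -slope")
    if (object@rmse < 0)
      msg <- c(msg, "rmse must be >= 0")
    if (object@r2 < 0 || object@r2 > 1 + 1e-12)
      msg <- c(msg, "r2 must lie in [0, 1]")
    if (object@nPoints != length(object@series@counts))
      msg <- c(msg, "nPoints must match the series length")
    if (length(msg)) msg else TRUE
  }
)
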