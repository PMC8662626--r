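#' Construct a LabelVolume
#'
#' Wraps a 3D array of integer region labels and its voxel spacing. Numeric
#' storage is accepted when every value is within `tol` of an integer
#' (scanner exports and `.npz` dumps are often float-typed); anything else is
#' a format error.
#'
#' @param data 3D array of region labels (integer, logical or near-integer
#'   numeric).
#' @param spacing numeric(3) voxel size in mm (default 1 mm isotropic).
#' @param tol largest tolerated deviation from an integer for numeric input.
#' @return a [LabelVolume-class].
#' @examples
#' vol <- labelVolume(array(0L, c(10, 10, 10)))
#' dim(vol)
#' @export
labelVolume <- function(data, spacing = c(1, 1, 1), tol = 1e-6) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("label volume must be a 3D array, got ",
         if (is.null(dim(data))) "a dimensionless vector"
         else paste0(length(dim(data)), "D"), call. = FALSE)
  if (is.logical(data) || is.integer(data)) {
    data <- array(as.integer(data), dim(data))
  } else if (is.double(data)) {
    if (anyNA(data) || max(abs(data - round(data))) > tol)
      stop("label volume contains non-integer values (beyond tolerance ",
           tol, ")", call. = FALSE)
    data <- array(as.integer(round(data)), dim(data))
  } else {
    stop("unsupported label volume storage mode: ", storage.mode(data),
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("LabelVolume", data = data, spacing = spacing)
}

#' @rdname accessors
#' @export
setMethod("volumeData", "LabelVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)

#' @describeIn labelVolume dimensions of the label array.
#' @param x a `LabelVolume`.
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@data))

setMethod("show", "LabelVolume", function(object) {
  labs <- sort(unique(as.vector(object@data)))
  labs <- labs[labs > 0L]
  cat("LabelVolume of dimension ", paste(dim(object@data), collapse = " x "),
      "\n  spacing (mm): ", paste(format(object@spacing), collapse = " x "),
      "\n  foreground voxels: ", sum(object@data > 0L),
      "\n  labels: ", if (length(labs)) paste(utils::head(labs, 12L),
                                              collapse = ", ") else "(none)",
      if (length(labs) > 12L) ", ..." else "", "\n", sep = "")
})

#' Check conformance with the 0--40 label-map convention
#'
#' The segmentation maps consumed here encode each structure with a unique
#' integer in 0--40 (0 = background). This predicate errors (or returns
#' `FALSE` with `strict = FALSE`) when a volume carries labels outside that
#' range.
#'
#' @param volume a [LabelVolume-class].
#' @param maxLabel largest allowed label (default 40).
#' @param strict error on violation instead of returning `FALSE`.
#' @return `TRUE` (invisibly) on conformance.
#' @export
checkLabelConformance <- function(volume, maxLabel = 40L, strict = TRUE) {
  stopifnot(is(volume, "LabelVolume"))
  bad <- max(volume@data)
  if (bad > maxLabel) {
    if (strict)
      stop("volume carries label ", bad, " > ", maxLabel,
           "; not a conformant label map", call. = FALSE)
    return(FALSE)
  }
  invisible(TRUE)
}

#' Centered crop of a label volume
#'
#' Returns the centered sub-block of exactly `targetShape`. When the margin
#' (source minus target) is odd along an axis, the low-index side keeps the
#' smaller offset, i.e. the extra voxel is dropped from the high-index side.
#' This is the geometry used to bring conformed 256-cube segmentations down
#' to the (160, 192, 224) grid expected by the downstream segmentation
#' network.
#'
#' @param volume a [LabelVolume-class].
#' @param targetShape integer(3), componentwise no larger than `dim(volume)`.
#' @return a [LabelVolume-class] of dimension `targetShape`, same spacing.
#' @examples
#' vol <- labelVolume(array(1L, c(5, 5, 5)))
#' dim(cropCenter(vol, c(2, 2, 2)))
#' @export
cropCenter <- function(volume, targetShape) {
  stopifnot(is(volume, "LabelVolume"))
  targetShape <- as.integer(targetShape)
  src <- dim(volume@data)
  if (length(targetShape) != 3L || any(targetShape < 1L))
    stop("targetShape must be three positive integers", call. = FALSE)
  if (any(targetShape > src))
    stop("target shape (", paste(targetShape, collapse = ","),
         ") exceeds source shape (", paste(src, collapse = ","), ")",
         call. = FALSE)
  off <- (src - targetShape) %/% 2L
  out <- volume@data[off[1] + seq_len(targetShape[1]),
                     off[2] + seq_len(targetShape[2]),
                     off[3] + seq_len(targetShape[3]), drop = FALSE]
  new("LabelVolume", data = out, spacing = volume@spacing)
}
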