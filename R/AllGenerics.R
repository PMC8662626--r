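#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes; use these rather
#' than reaching into slots.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' @rdname accessors
#' @export
setGeneric("epsilons", function(x) standardGeneric("epsilons"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("fd", function(x) standardGeneric("fd"))

#' @rdname accessors
#' @export
setGeneric("fdSlope", function(x) standardGeneric("fdSlope"))

#' @rdname accessors
#' @export
setGeneric("fdIntercept", function(x) standardGeneric("fdIntercept"))

#' @rdname accessors
#' @export
setGeneric("rmse", function(x) standardGeneric("rmse"))

#' @rdname accessors
#' @export
setGeneric("rsquared", function(x) standardGeneric("rsquared"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("countSeries", function(x) standardGeneric("countSeries"))

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
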