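#' Synthetic 3D masks of known dimension
#'
#' Test structures for the box-counting estimator, each with an analytically
#' known dimension: `filled_cube` (3), `slab` (a `size x size x 1` plane, 2),
#' `line` (`size x 1 x 1`, 1), `menger_sponge` (similarity dimension
#' log 20 / log 3 = 2.7268...) and `random_blob` (seeded thresholded
#' smoothed noise; no analytic dimension -- used for counting-oracle tests,
#' not dimension recovery).
#'
#' The level-`L` Menger sponge occupies a `(3^L)^3` grid with exactly `20^L`
#' solid voxels: each refinement keeps the 20 of 27 subcells whose base-3
#' coordinate digits include at most one middle digit (removing the 6 face
#' centers and the body center).
#'
#' @param kind one of `"filled_cube"`, `"slab"`, `"line"`,
#'   `"menger_sponge"`, `"random_blob"`.
#' @param size edge length in voxels (all kinds except the sponge); >= 2.
#' @param level sponge recursion level; >= 1.
#' @param seed integer seed (`random_blob` only); required for that kind.
#' @param density target foreground fraction of `random_blob`.
#' @return a 3D logical array.
#' @examples
#' sum(makePhantom("menger_sponge", level = 2))  # 20^2 = 400
#' dim(makePhantom("slab", size = 8))
#' @export
makePhantom <- function(kind = c("filled_cube", "slab", "line",
                                 "menger_sponge", "random_blob"),
                        size = 64L, level = 3L, seed = NULL,
                        density = 0.3) {
  kind <- match.arg(kind)
  if (kind == "menger_sponge") {
    level <- as.integer(level)
    if (is.na(level) || level < 1L)
      stop("menger_sponge needs level >= 1", call. = FALSE)
    return(.mengerSponge(level))
  }
  size <- as.integer(size)
  if (is.na(size) || size < 2L)
    stop(kind, " needs size >= 2", call. = FALSE)
  switch(kind,
    filled_cube = array(TRUE, c(size, size, size)),
    slab = array(TRUE, c(size, size, 1L)),
    line = array(TRUE, c(size, 1L, 1L)),
    random_blob = {
      if (is.null(seed))
        stop("random_blob needs a seed", call. = FALSE)
      .randomBlob(size, seed, density)
    })
}

# occupied iff, at every refinement level, at most one of the three base-3
# coordinate digits equals 1
.mengerSponge <- function(level) {
  n <- 3L^level
  digitIsMid <- matrix(FALSE, level, n)
  v <- 0:(n - 1L)
  for (d in seq_len(level)) {
    digitIsMid[d, ] <- (v %% 3L) == 1L
    v <- v %/% 3L
  }
  occ <- array(TRUE, c(n, n, n))
  for (d in seq_len(level)) {
    a <- digitIsMid[d, ]
    occ <- occ & (outer(outer(a, a, "+"), a, "+") <= 1L)
  }
  occ
}

# seeded smoothed-noise blob: uniform noise, one pass of 3^3 box smoothing,
# thresholded at the (1 - density) quantile
.randomBlob <- function(size, seed, density) {
  stopifnot(density > 0, density < 1)
  noise <- withSeed(seed, array(stats::runif(size^3), rep(size, 3L)))
  sm <- .boxSmooth(noise)
  sm >= stats::quantile(sm, 1 - density)
}

# 3x3x3 mean filter with edge replication, by shift-and-add along each axis
.boxSmooth <- function(a) {
  n <- dim(a)
  sh <- function(x, axis, by) {
    idx <- pmin(pmax(seq_len(n[axis]) + by, 1L), n[axis])
    switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  }
  for (axis in 1:3)
    a <- (sh(a, axis, -1L) + a + sh(a, axis, 1L)) / 3
  a
}

#' Embed a mask into a label volume
#'
#' Places a binary phantom mask, centered, into a zero (background) volume
#' of the requested shape, carrying the given region label. With an odd
#' margin the extra voxel sits on the high-index side, mirroring the
#' [cropCenter()] convention, so embedding at a volume's shape and cropping
#' back round-trips exactly.
#'
#' @param mask 3D logical/numeric array.
#' @param volumeShape integer(3), componentwise >= `dim(mask)`.
#' @param label region label in 1..40 (0 is reserved for background).
#' @param spacing voxel size of the produced volume, mm.
#' @return a [LabelVolume-class].
#' @examples
#' vol <- embedPhantom(makePhantom("menger_sponge", level = 2),
#'                     c(16, 16, 16), label = 26)
#' sum(volumeData(vol) == 26)  # 400
#' @export
embedPhantom <- function(mask, volumeShape, label, spacing = c(1, 1, 1)) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  label <- as.integer(label)
  if (is.na(label) || label < 1L || label > 40L)
    stop("label must lie in 1..40 (0 is background)", call. = FALSE)
  volumeShape <- as.integer(volumeShape)
  ms <- dim(mask)
  if (length(volumeShape) != 3L || any(volumeShape < ms))
    stop("mask of shape (", paste(ms, collapse = ","),
         ") does not fit in (", paste(volumeShape, collapse = ","), ")",
         call. = FALSE)
  off <- (volumeShape - ms) %/% 2L
  data <- array(0L, volumeShape)
  data[off[1] + seq_len(ms[1]), off[2] + seq_len(ms[2]),
       off[3] + seq_len(ms[3])] <- label * (mask != 0)
  labelVolume(data, spacing = spacing)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the given seed and restores the caller's RNG state
#' afterwards, so seeded generators (blobs, fold assignment) do not disturb
#' the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Analytic dimension of a phantom kind
#'
#' @param kind phantom kind as in [makePhantom()].
#' @return the expected dimension, or `NA` for `random_blob`.
#' @export
expectedFD <- function(kind) {
  switch(kind,
    filled_cube = 3,
    slab = 2,
    line = 1,
    menger_sponge = log(20) / log(3),
    random_blob = NA_real_,
    stop("unknown phantom kind: ", kind, call. = FALSE))
}
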