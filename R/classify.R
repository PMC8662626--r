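#' F-beta score
#'
#' \deqn{F_\beta = (1+\beta^2)\,P\,R / (\beta^2 P + R)}
#' with the convention \eqn{F_\beta = 0} when precision and recall are both
#' zero. `beta > 1` weights recall over precision; the default 8.25 matches
#' a control:dementia imbalance of that ratio, penalising missed dementia
#' cases (false negatives) far more than false alarms.
#'
#' @param precision,recall numeric in [0, 1] (vectorised).
#' @param beta positive weight.
#' @return the F-beta score(s) in [0, 1].
#' @examples
#' fbetaScore(0.5, 1, 8.25)
#' fbetaScore(0.7, 0.7, 1)     # == 0.7 for any beta
#' @export
fbetaScore <- function(precision, recall, beta = 8.25) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a single positive number", call. = FALSE)
  if (any(precision < 0 | precision > 1, na.rm = TRUE) ||
      any(recall < 0 | recall > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

.classMetrics <- function(truth, pred, positive, beta) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = precision, recall = recall,
    fbeta = fbetaScore(precision, recall, beta),
    accuracy = mean(truth == pred))
}

#' Cross-validated SVM classification of regional features
#'
#' Trains a support vector machine on per-subject feature rows (by default
#' the `volume` and `fd` columns) under stratified k-fold cross-validation
#' and reports pooled test-set precision, recall, F-beta and accuracy, with
#' dementia as the positive class. Features are standardized inside each
#' fold (fit on the training split, applied to the test split): volumes in
#' mm^3 and dimensionless FD values differ by orders of magnitude, and an
#' unscaled kernel would see only the volume axis. Defaults follow the
#' reference configuration: RBF kernel, `C = 100`, `gamma = 6`, five folds,
#' `beta = 8.25`.
#'
#' @param rows `data.frame` with the feature columns and a `class_label`
#'   column holding `"control"` / `"dementia"` (any two labels work; set
#'   `positive` accordingly).
#' @param features character vector of feature column names.
#' @param kernel `"radial"`, `"linear"` or `"polynomial"` (e1071 names;
#'   `"rbf"` and `"poly"` are accepted aliases).
#' @param C,gamma SVM cost and kernel width, both > 0.
#' @param nFolds number of folds (>= 2); reduced with a warning when the
#'   minority class is smaller than the fold count.
#' @param beta F-beta weight.
#' @param seed integer seed fixing the fold assignment.
#' @param positive label of the positive class.
#' @return a list of class `classifierReport`: pooled `precision`,
#'   `recall`, `fbeta`, `accuracy`, per-fold metrics (`perFold`), the fold
#'   assignment, and a final model (`model`, with its standardization
#'   `center`/`scale`) refit on all rows for inspection such as
#'   [decisionBoundaryGrid()].
#' @export
crossvalClassify <- function(rows, features = c("volume", "fd"),
                             kernel = "radial", C = 100, gamma = 6,
                             nFolds = 5L, beta = 8.25, seed = 17L,
                             positive = "dementia") {
  stopifnot(is.data.frame(rows))
  if (!all(features %in% names(rows)))
    stop("missing feature columns: ",
         paste(setdiff(features, names(rows)), collapse = ", "),
         call. = FALSE)
  alias <- c(rbf = "radial", poly = "polynomial")[kernel]
  if (!is.na(alias)) kernel <- unname(alias)
  if (!kernel %in% c("radial", "linear", "polynomial"))
    stop("unsupported kernel", call. = FALSE)
  if (C <= 0 || gamma <= 0) stop("C and gamma must be > 0", call. = FALSE)
  truth <- as.character(rows$class_label)
  classes <- unique(truth)
  if (length(classes) < 2L)
    stop("both classes must be present", call. = FALSE)
  x <- as.matrix(rows[, features, drop = FALSE])
  if (anyNA(x)) stop("features contain NA", call. = FALSE)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2", call. = FALSE)
  minority <- min(table(truth))
  if (nFolds > minority) {
    warning("fold count ", nFolds, " exceeds minority class size ",
            minority, "; reducing", call. = FALSE)
    nFolds <- max(2L, as.integer(minority))
  }
  # stratified fold ids: within each class, cycle 1..k in random order
  fold <- integer(length(truth))
  withSeed(seed, for (cl in classes) {
    idx <- which(truth == cl)
    fold[idx] <- sample(rep(seq_len(nFolds), length.out = length(idx)))
  })
  pred <- character(length(truth))
  perFold <- vector("list", nFolds)
  for (k in seq_len(nFolds)) {
    test <- fold == k
    ctr <- colMeans(x[!test, , drop = FALSE])
    scl <- apply(x[!test, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
    xtr <- scale(x[!test, , drop = FALSE], ctr, scl)
    xte <- scale(x[test, , drop = FALSE], ctr, scl)
    fit <- e1071::svm(xtr, factor(truth[!test]), kernel = kernel,
                      cost = C, gamma = gamma, scale = FALSE)
    pred[test] <- as.character(stats::predict(fit, xte))
    perFold[[k]] <- .classMetrics(truth[test], pred[test], positive, beta)
  }
  pooled <- .classMetrics(truth, pred, positive, beta)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  finalFit <- e1071::svm(scale(x, ctr, scl), factor(truth),
                         kernel = kernel, cost = C, gamma = gamma,
                         scale = FALSE)
  structure(list(
    precision = unname(pooled["precision"]),
    recall = unname(pooled["recall"]),
    fbeta = unname(pooled["fbeta"]),
    accuracy = unname(pooled["accuracy"]),
    perFold = do.call(rbind, lapply(perFold, function(m)
      as.data.frame(as.list(m)))),
    fold = fold, prediction = pred, positive = positive,
    features = features, beta = beta,
    model = finalFit, center = ctr, scale = scl),
    class = "classifierReport")
}

#' @export
print.classifierReport <- function(x, ...) {
  cat(sprintf(paste0(
    "SVM cross-validation report (positive class: %s)\n",
    "  precision %.4f  recall %.4f  F(beta=%g) %.4f  accuracy %.4f\n",
    "  %d folds, features: %s\n"),
    x$positive, x$precision, x$recall, x$beta, x$fbeta, x$accuracy,
    nrow(x$perFold), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Decision boundary grid of a fitted 2-feature model
#'
#' Evaluates the report's final model over a rectangular grid in the
#' original (unstandardized) feature units, for plotting the decision
#' boundary between the classes.
#'
#' @param report a `classifierReport` from [crossvalClassify()] on exactly
#'   two features.
#' @param xlim,ylim grid bounds for the first/second feature; defaults span
#'   the training range.
#' @param n grid points per axis.
#' @return `data.frame` with the two feature columns and the predicted
#'   `class`.
#' @export
decisionBoundaryGrid <- function(report, xlim = NULL, ylim = NULL,
                                 n = 50L) {
  stopifnot(inherits(report, "classifierReport"))
  if (length(report$features) != 2L)
    stop("decision boundary grid needs exactly 2 features", call. = FALSE)
  rng <- function(lim, i) {
    if (!is.null(lim)) return(lim)
    c(report$center[i] - 3 * report$scale[i],
      report$center[i] + 3 * report$scale[i])
  }
  xs <- seq(rng(xlim, 1L)[1], rng(xlim, 1L)[2], length.out = n)
  ys <- seq(rng(ylim, 2L)[1], rng(ylim, 2L)[2], length.out = n)
  grid <- as.matrix(expand.grid(xs, ys))
  colnames(grid) <- report$features
  std <- scale(grid, report$center, report$scale)
  out <- as.data.frame(grid)
  out$class <- as.character(stats::predict(report$model, std))
  out
}
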