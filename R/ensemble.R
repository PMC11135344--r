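# ert(): bagged / random-forest ensembles of surrogate-split regression
# trees.  bootstrap = TRUE with mtry_fraction = 1 is pure bagging;
# mtry_fraction < 1 adds random-forest feature subsampling.  Predictions
# are the unweighted mean over trees; importance the elementwise mean of
# per-tree importances.

#' Ensemble regression trees with surrogate splits
#'
#' Fits `n_trees` surrogate-split regression trees (see [ert_tree()]), each
#' on an independent bootstrap resample of the rows (when `bootstrap`),
#' with `mtry = max(1, round(mtry_fraction * p))` features sampled per
#' node.  `mtry_fraction = 1` with `bootstrap = TRUE` is the classic bagged
#' tree; the default 1/3 is random-forest-style feature subsampling.
#' Learner seeds are derived deterministically from `seed`, so identical
#' inputs give bit-identical ensembles.
#'
#' @param x Feature matrix, or a formula.
#' @param ... Passed between methods.
#' @return An object of class `ert` with elements `trees` (list of
#'   `ert_tree`, when `keep_trees`), `importance` (mean per-feature
#'   node-risk importance), and the fitting configuration.
#' @export
ert <- function(x, ...) UseMethod("ert")

#' @rdname ert
#' @param y Numeric response.
#' @param n_trees Number of learners (default 50).
#' @param bootstrap Resample rows with replacement per learner.
#' @param mtry_fraction Fraction of features considered per node, in
#'   (0, 1].
#' @param min_leaf Minimum samples per leaf.
#' @param max_surrogates Surrogates retained per branch node.
#' @param seed Integer seed.
#' @param keep_trees Materialize individual trees (needed by
#'   [predict.ert()]; turn off for importance-only fits at scale).
#' @export
ert.default <- function(x, y, n_trees = 50L, bootstrap = TRUE,
                        mtry_fraction = 1 / 3, min_leaf = 5L,
                        max_surrogates = 10L, seed = 1L,
                        keep_trees = TRUE, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y have mismatched lengths")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(y) < 2 * min_leaf)
    stop("need at least 2 * min_leaf = ", 2 * min_leaf, " samples")
  if (mtry_fraction <= 0 || mtry_fraction > 1)
    stop("mtry_fraction must be in (0, 1]")
  p <- ncol(x)
  mtry <- max(1L, as.integer(round(mtry_fraction * p)))
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("X", seq_len(p))
  raw <- cpp_grow_forest(x, y, as.integer(n_trees), isTRUE(bootstrap),
                         mtry, as.integer(min_leaf),
                         as.integer(max_surrogates), as.integer(seed),
                         isTRUE(keep_trees))
  params <- list(min_leaf = as.integer(min_leaf), mtry = mtry,
                 max_surrogates = as.integer(max_surrogates),
                 seed = as.integer(seed))
  trees <- NULL
  if (isTRUE(keep_trees))
    trees <- lapply(raw$trees, .wrap_tree, feature_names = fn,
                    params = params)
  structure(
    list(trees = trees, feature_count = p, feature_names = fn,
         importance = stats::setNames(as.numeric(raw$importance), fn),
         config = list(n_trees = as.integer(n_trees),
                       bootstrap = isTRUE(bootstrap),
                       mtry_fraction = mtry_fraction, mtry = mtry,
                       min_leaf = as.integer(min_leaf),
                       max_surrogates = as.integer(max_surrogates),
                       seed = as.integer(seed)),
         n = nrow(x), call = match.call()),
    class = "ert"
  )
}

#' @rdname ert
#' @param data data.frame holding the formula's variables; all right-hand
#'   side terms must be numeric.
#' @param formula Model formula, e.g. `mmse ~ .`.
#' @export
ert.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as.matrix(mf[-1L])
  fit <- ert.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.ert <- function(x, ...) {
  cat("Ensemble regression tree (surrogate splits)\n")
  cat(sprintf("  %d trees, mtry %d/%d, min_leaf %d, bootstrap %s\n",
              x$config$n_trees, x$config$mtry, x$feature_count,
              x$config$min_leaf, x$config$bootstrap))
  cat("  fitted on", x$n, "samples\n")
  invisible(x)
}

#' @export
summary.ert <- function(object, n_top = 10L, ...) {
  imp <- sort(importance(object), decreasing = TRUE)
  out <- list(config = object$config, n = object$n,
              top_importance = utils::head(imp, n_top))
  class(out) <- "summary.ert"
  out
}

#' @export
print.summary.ert <- function(x, ...) {
  cat("ert ensemble:", x$config$n_trees, "trees on", x$n, "samples\n")
  cat("top features by node-risk importance:\n")
  print(round(x$top_importance, 6))
  invisible(x)
}

#' @export
predict.ert <- function(object, newdata, ...) {
  if (is.null(object$trees))
    stop("ensemble was fitted with keep_trees = FALSE; refit to predict")
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$feature_count)
    stop("newdata has ", ncol(newdata), " columns; ensemble expects ",
         object$feature_count)
  preds <- vapply(object$trees, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  rowMeans(as.matrix(preds))
}

#' @rdname importance
#' @export
importance.ert <- function(object, ...) object$importance
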