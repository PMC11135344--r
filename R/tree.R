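# Single surrogate-split regression trees: the building block of ert().
# Growth, prediction and importance are implemented in compiled code
# (src/ert_tree.cpp); this file provides the R-facing object, methods, a
# pure-R importance recomputation used as a cross-check, and JSON
# serialization.

.wrap_tree <- function(raw, feature_names, params) {
  nb <- raw$n_branch
  feat <- raw$feature
  leaf <- feat < 0L
  nodes <- data.frame(
    node_id = seq_along(feat),
    left = ifelse(leaf, NA_integer_, raw$left + 1L),
    right = ifelse(leaf, NA_integer_, raw$right + 1L),
    feature = ifelse(leaf, NA_integer_, feat + 1L),
    threshold = ifelse(leaf, NA_real_, raw$threshold),
    n = raw$n, probability = raw$prob, mse = raw$mse, risk = raw$risk,
    prediction = raw$pred,
    risk_reduction = ifelse(leaf, NA_real_, raw$risk_reduction)
  )
  surrogates <- lapply(raw$surrogates, function(sm) {
    if (!nrow(sm)) {
      return(data.frame(feature = integer(), threshold = numeric(),
                        association = numeric(),
                        risk_reduction = numeric()))
    }
    data.frame(feature = as.integer(sm[, 1]) + 1L, threshold = sm[, 2],
               association = sm[, 3], risk_reduction = sm[, 4])
  })
  structure(
    list(nodes = nodes, surrogates = surrogates, n_branch_nodes = nb,
         feature_count = length(feature_names),
         feature_names = feature_names,
         importance = stats::setNames(as.numeric(raw$importance),
                                      feature_names),
         params = params),
    class = "ert_tree"
  )
}

#' Fit a single surrogate-split regression tree
#'
#' Greedy recursive binary partitioning.  At each node the split maximising
#' the node-risk reduction (parent risk minus the children's summed risk;
#' risk = node MSE weighted by the node's training-sample probability) is
#' chosen over an `mtry`-subset of features; thresholds are midpoints
#' between adjacent distinct values, ties break to the lowest feature index
#' then lowest threshold.  After the primary split, up to `max_surrogates`
#' surrogate splits with positive predictive association are attached: for
#' each other feature, the threshold best mimicking the primary left/right
#' partition, with association lambda = (min(pL,pR) - (1 - p_agree)) /
#' min(pL,pR), and that partition's own risk reduction on the node's
#' response.  Surrogates are kept in order of association, ties broken by
#' risk reduction then feature index (association ties are common, and an
#' index-only tie-break would bias importance toward low-index features
#' when the list is truncated).  Growth stops when no split reduces risk
#' or a child would hold fewer than `min_leaf` samples.
#'
#' @param x Numeric feature matrix (no missing values).
#' @param y Numeric response.
#' @param min_leaf Minimum samples per leaf (default 5).
#' @param mtry Features sampled per node; `NULL` means all.
#' @param max_surrogates Surrogates retained per branch node (default 10).
#' @param seed Integer seed for the per-node feature subsampling.
#' @return An object of class `ert_tree` with a `nodes` table (one row per
#'   node: children, split, n, probability, mse, risk, prediction, risk
#'   reduction), per-node `surrogates` tables, `n_branch_nodes` and the
#'   per-feature `importance` vector.
#' @examples
#' x <- matrix(0:3, ncol = 1)
#' fit <- ert_tree(x, c(0, 0, 10, 10), min_leaf = 1)
#' fit$nodes[1, c("threshold", "risk_reduction")]  # split at 1.5, reduction 25
#' @export
ert_tree <- function(x, y, min_leaf = 5L, mtry = NULL,
                     max_surrogates = 10L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) stop("x and y have mismatched lengths")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (is.null(mtry)) mtry <- ncol(x)
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("X", seq_len(ncol(x)))
  raw <- cpp_grow_forest(x, as.numeric(y), 1L, FALSE, as.integer(mtry),
                         as.integer(min_leaf), as.integer(max_surrogates),
                         as.integer(seed), TRUE)
  tr <- raw$trees[[1]]
  .wrap_tree(tr, fn, list(min_leaf = as.integer(min_leaf),
                          mtry = as.integer(mtry),
                          max_surrogates = as.integer(max_surrogates),
                          seed = as.integer(seed)))
}

#' @export
print.ert_tree <- function(x, ...) {
  cat("ert_tree:", nrow(x$nodes), "nodes (", x$n_branch_nodes,
      "branch ),", x$feature_count, "features\n")
  cat("root risk:", format(x$nodes$risk[1]), "\n")
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("importance (nonzero):\n")
    print(utils::head(top, 10))
  }
  invisible(x)
}

#' @export
predict.ert_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$feature_count)
    stop("newdata has ", ncol(newdata), " columns; tree expects ",
         object$feature_count)
  nd <- object$nodes
  leaf <- is.na(nd$feature)
  cpp_predict_tree(
    ifelse(leaf, -1L, nd$feature - 1L),
    ifelse(leaf, 0, nd$threshold),
    ifelse(leaf, -1L, nd$left - 1L),
    ifelse(leaf, -1L, nd$right - 1L),
    nd$prediction, newdata
  )
}

#' Per-feature predictor importance
#'
#' Sum of node-risk reductions of every split on the feature - primary and
#' surrogate - over all branch nodes, divided by the number of branch
#' nodes.  For an ensemble, the elementwise mean over trees.
#'
#' @param object A fitted `ert_tree` or `ert` object.
#' @param ... Unused.
#' @return Named numeric vector, one entry per feature, all `>= 0`.
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.ert_tree <- function(object, ...) object$importance

#' Recompute tree importance from the serialized node structure
#'
#' Pure-R recomputation of [importance()] from the `nodes` and `surrogates`
#' tables of a fitted tree; exists as an independent route for verifying the
#' compiled implementation.
#'
#' @param tree An `ert_tree`.
#' @return Named numeric vector of per-feature importance.
#' @export
recompute_importance <- function(tree) {
  imp <- stats::setNames(numeric(tree$feature_count), tree$feature_names)
  if (tree$n_branch_nodes == 0) return(imp)
  nd <- tree$nodes
  for (i in seq_len(nrow(nd))) {
    if (is.na(nd$feature[i])) next
    imp[nd$feature[i]] <- imp[nd$feature[i]] + nd$risk_reduction[i]
    s <- tree$surrogates[[i]]
    for (j in seq_len(nrow(s)))
      imp[s$feature[j]] <- imp[s$feature[j]] + s$risk_reduction[j]
  }
  imp / tree$n_branch_nodes
}

#' Serialize a fitted tree to JSON
#'
#' @param tree An `ert_tree`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ert_tree <- function(tree, path) {
  .write_json(unclass(tree), path)
  invisible(path)
}

#' Read a serialized tree back from JSON
#'
#' @param path File written by [write_ert_tree()].
#' @return An `ert_tree`.
#' @export
read_ert_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$surrogates <- lapply(obj$surrogates, function(s) {
    if (is.null(s) || !length(s)) {
      return(data.frame(feature = integer(), threshold = numeric(),
                        association = numeric(),
                        risk_reduction = numeric()))
    }
    as.data.frame(s)
  })
  obj$importance <- stats::setNames(as.numeric(obj$importance),
                                    obj$feature_names)
  class(obj) <- "ert_tree"
  obj
}
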