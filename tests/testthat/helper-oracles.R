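# Brute-force oracles for the tree core: exhaustive enumeration over all
# feature/threshold pairs, independent of the compiled implementation.

`%+%` <- function(a, b) paste0(a, b)

oracle_sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)

# best primary split by exhaustive search; ties go to lowest feature index
# then lowest threshold (thresholds scanned ascending, strict improvement
# with a relative tolerance so floating-point noise cannot flip
# mathematically tied gains)
oracle_best_split <- function(X, y, min_leaf) {
  tol <- 1e-12 * oracle_sse(y)
  best <- list(gain = 0, f = NA_integer_, thr = NA_real_)
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (k in seq_len(length(xs) - 1)) {
      thr <- (xs[k] + xs[k + 1]) / 2
      L <- X[, f] < thr
      if (sum(L) < min_leaf || sum(!L) < min_leaf) next
      gain <- oracle_sse(y) - oracle_sse(y[L]) - oracle_sse(y[!L])
      if (gain > best$gain + tol) best <- list(gain = gain, f = f,
                                               thr = thr)
    }
  }
  best
}

# surrogates by exhaustive search: per feature the max-agreement threshold
# (left_if_less), lambda > 0 kept, ordered by lambda desc then feature asc
oracle_surrogates <- function(X, y, f_primary, thr, n_root,
                              max_surr = 10) {
  n <- nrow(X)
  go_left <- X[, f_primary] < thr
  minp <- min(sum(go_left), sum(!go_left)) / n
  out <- data.frame(feature = integer(), threshold = numeric(),
                    association = numeric(), risk_reduction = numeric())
  if (minp == 0) return(out)
  for (f in seq_len(ncol(X))) {
    if (f == f_primary) next
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    best <- NULL
    for (k in seq_len(length(xs) - 1)) {
      t2 <- (xs[k] + xs[k + 1]) / 2
      L <- X[, f] < t2
      agree <- sum(L & go_left) + sum(!L & !go_left)
      if (is.null(best) || agree > best$agree)
        best <- list(agree = agree, thr = t2)
    }
    lambda <- (minp - (1 - best$agree / n)) / minp
    if (lambda <= 0) next
    L <- X[, f] < best$thr
    gain <- oracle_sse(y) - oracle_sse(y[L]) - oracle_sse(y[!L])
    out <- rbind(out, data.frame(feature = f, threshold = best$thr,
                                 association = lambda,
                                 risk_reduction = gain / n_root))
  }
  out <- out[order(-out$association, -out$risk_reduction, out$feature),
             , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_surr)
}

# full oracle tree grown recursively with the same stopping rules
oracle_tree <- function(X, y, min_leaf, max_surr = 10) {
  n_root <- nrow(X)
  build <- function(rows) {
    yv <- y[rows]
    sse <- oracle_sse(yv)
    node <- list(rows = rows, risk = sse / n_root, pred = mean(yv))
    if (length(rows) < 2 * min_leaf || sse <= 0) return(node)
    b <- oracle_best_split(X[rows, , drop = FALSE], yv, min_leaf)
    if (is.na(b$f) || b$gain <= 0) return(node)
    node$feature <- b$f
    node$threshold <- b$thr
    node$rr <- b$gain / n_root
    node$surr <- oracle_surrogates(X[rows, , drop = FALSE], yv, b$f,
                                   b$thr, n_root, max_surr)
    L <- X[rows, b$f] < b$thr
    node$left <- build(rows[L])
    node$right <- build(rows[!L])
    node
  }
  build(seq_len(n_root))
}

oracle_importance <- function(otree, p) {
  imp <- numeric(p)
  n_branch <- 0L
  walk <- function(nd) {
    if (is.null(nd$feature)) return()
    n_branch <<- n_branch + 1L
    imp[nd$feature] <<- imp[nd$feature] + nd$rr
    for (j in seq_len(nrow(nd$surr)))
      imp[nd$surr$feature[j]] <<- imp[nd$surr$feature[j]] +
        nd$surr$risk_reduction[j]
    walk(nd$left)
    walk(nd$right)
  }
  walk(otree)
  if (n_branch == 0) imp else imp / n_branch
}

# canonical surrogate order: mathematically tied (lambda, risk reduction)
# pairs may be permuted by floating-point summation order, so both sides
# are re-sorted on values rounded to 9 significant digits before comparing
canon_surr <- function(s) {
  if (!nrow(s)) return(s)
  o <- order(-signif(s$association, 9), -signif(s$risk_reduction, 9),
             s$feature)
  s <- s[o, , drop = FALSE]
  rownames(s) <- NULL
  s
}

# compare a fitted ert_tree with the oracle tree node by node
expect_tree_matches_oracle <- function(fit, otree, tol = 1e-9) {
  nd <- fit$nodes
  cmp <- function(i, onode) {
    if (is.null(onode$feature)) {
      expect_true(is.na(nd$feature[i]))
      return(invisible())
    }
    expect_identical(nd$feature[i], as.integer(onode$feature))
    expect_equal(nd$threshold[i], onode$threshold, tolerance = tol)
    expect_equal(nd$risk_reduction[i], onode$rr, tolerance = tol)
    s <- canon_surr(fit$surrogates[[i]])
    os <- canon_surr(onode$surr)
    expect_identical(s$feature, as.integer(os$feature))
    expect_equal(s$threshold, os$threshold, tolerance = tol)
    expect_equal(s$association, os$association, tolerance = tol)
    expect_equal(s$risk_reduction, os$risk_reduction, tolerance = tol)
    cmp(nd$left[i], onode$left)
    cmp(nd$right[i], onode$right)
  }
  cmp(1L, otree)
}

# conservation: sum of primary risk reductions = root risk - leaf risks
expect_risk_conservation <- function(tree, tol = 1e-9) {
  nd <- tree$nodes
  leaf_risk <- sum(nd$risk[is.na(nd$feature)])
  total_rr <- sum(nd$risk_reduction, na.rm = TRUE)
  expect_equal(total_rr, nd$risk[1] - leaf_risk,
               tolerance = tol * max(1, abs(nd$risk[1])))
}

# small deterministic regression data
tiny_data <- function(seed, n = 12, p = 3) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), y = rnorm(n))
}
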