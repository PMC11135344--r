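# Repeated random train/test resampling (default 90/10) of the ensemble,
# and the label-shuffled permutation runs that define the NI null.

.fit_eval_once <- function(X, y, train_idx, n_trees, bootstrap, mtry,
                           min_leaf, max_surrogates, seed) {
  Xtr <- X[train_idx, , drop = FALSE]
  Xte <- X[-train_idx, , drop = FALSE]
  yte <- y[-train_idx]
  raw <- cpp_grow_forest(Xtr, y[train_idx], n_trees, bootstrap, mtry,
                         min_leaf, max_surrogates, seed, FALSE, Xte)
  pred <- raw$test_pred
  corr <- NA_real_
  if (length(yte) >= 2 && stats::sd(pred) > 0 && stats::sd(yte) > 0)
    corr <- stats::cor(pred, yte)
  list(mse = mean((pred - yte)^2), corr = corr,
       importance = as.numeric(raw$importance))
}

.draw_train <- function(n, train_frac, stratify = NULL) {
  if (is.null(stratify)) {
    n_train <- round(train_frac * n)
    if (n_train >= n || n_train < 1)
      stop("train_frac leaves an empty train or test set")
    sort(sample.int(n, n_train))
  } else {
    idx <- unlist(lapply(split(seq_len(n), stratify), function(g) {
      k <- round(train_frac * length(g))
      k <- min(max(k, 1L), length(g) - 1L)
      sample(g, k)
    }), use.names = FALSE)
    sort(idx)
  }
}

#' Repeated train/test evaluation of the ensemble
#'
#' Repeats `n_iter` times: draw a uniformly random train/test partition
#' (train size `round(train_frac * n)`), fit an [ert()] ensemble on the
#' training rows, and record the held-out MSE, the Pearson correlation
#' between predicted and actual test scores, and the ensemble importance
#' vector.  All randomness is a deterministic function of `seed` and the
#' iteration index.  A test set with fewer than 2 points, or zero-variance
#' predictions, leaves that iteration's correlation undefined (`NA`,
#' counted); the MSE is still recorded.
#'
#' @param X Feature matrix.
#' @param y Numeric response.
#' @param n_iter Number of iterations (default 100; the full-scale protocol
#'   uses 500).
#' @param train_frac Training fraction (default 0.9).
#' @param n_trees,bootstrap,mtry_fraction,min_leaf,max_surrogates Ensemble
#'   parameters, as in [ert()].
#' @param stratify Optional factor (length n); when given, the train
#'   partition is drawn within each level.
#' @param seed Integer seed.
#' @return Object of class `ert_resample`: vectors `mse` and `corr`
#'   (length `n_iter`), matrix `importance` (`n_iter x p`), per-iteration
#'   `seeds`, and bookkeeping fields.
#' @export
ert_resample <- function(X, y, n_iter = 100L, train_frac = 0.9,
                         n_trees = 50L, bootstrap = TRUE,
                         mtry_fraction = 1 / 3, min_leaf = 5L,
                         max_surrogates = 10L, stratify = NULL,
                         seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y have mismatched lengths")
  p <- ncol(X)
  mtry <- max(1L, as.integer(round(mtry_fraction * p)))
  mse <- corr <- numeric(n_iter)
  seeds <- integer(n_iter)
  imp <- matrix(NA_real_, n_iter, p,
                dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n_iter)) {
    seeds[i] <- .derive_seed(seed, i, 1L)
    train_idx <- .with_seed(seeds[i],
                            .draw_train(n, train_frac, stratify))
    r <- .fit_eval_once(X, y, train_idx, as.integer(n_trees),
                        isTRUE(bootstrap), mtry, as.integer(min_leaf),
                        as.integer(max_surrogates),
                        .derive_seed(seed, i, 2L))
    mse[i] <- r$mse
    corr[i] <- r$corr
    imp[i, ] <- r$importance
  }
  n_undef <- sum(is.na(corr))
  if (n_undef > 0)
    message(n_undef, " iteration(s) had undefined test correlation")
  structure(
    list(mse = mse, corr = corr, importance = imp, seeds = seeds,
         n_iter = as.integer(n_iter), train_frac = train_frac,
         n = n, p = p, n_undefined_corr = n_undef,
         config = list(n_trees = as.integer(n_trees),
                       bootstrap = isTRUE(bootstrap),
                       mtry_fraction = mtry_fraction, mtry = mtry,
                       min_leaf = as.integer(min_leaf),
                       max_surrogates = as.integer(max_surrogates),
                       seed = as.integer(seed),
                       stratified = !is.null(stratify))),
    class = "ert_resample"
  )
}

#' @export
print.ert_resample <- function(x, ...) {
  cat(sprintf("ert_resample: %d iterations, %d/%d train/test of n=%d\n",
              x$n_iter, round(x$train_frac * x$n),
              x$n - round(x$train_frac * x$n), x$n))
  ok <- !is.na(x$corr)
  cat(sprintf("  test MSE  %.3f +/- %.3f\n", mean(x$mse),
              stats::sd(x$mse)))
  if (any(ok))
    cat(sprintf("  test corr %.3f +/- %.3f (%d undefined)\n",
                mean(x$corr[ok]), stats::sd(x$corr[ok]), sum(!ok)))
  invisible(x)
}

#' @export
summary.ert_resample <- function(object, ...) {
  ok <- !is.na(object$corr)
  data.frame(
    n_iter = object$n_iter,
    mse_mean = mean(object$mse), mse_sd = stats::sd(object$mse),
    corr_mean = if (any(ok)) mean(object$corr[ok]) else NA_real_,
    corr_sd = if (sum(ok) > 1) stats::sd(object$corr[ok]) else NA_real_,
    corr_undefined = sum(!ok)
  )
}

#' Label-shuffled permutation null for NI
#'
#' Repeats `n_perm` times: shuffle the response uniformly at random, run
#' one train/test iteration exactly as in [ert_resample()], and compute
#' that run's normalized importance (square root of the importance vector
#' rescaled to mean one).  The shuffle uses randomness independent of the
#' split draw.  Runs in which the ensemble records no splits at all yield
#' an `NA` NI row (counted and messaged).
#'
#' @inheritParams ert_resample
#' @param n_perm Number of permutation runs (default 100; full-scale
#'   protocol 500).
#' @return Object of class `ert_permnull`: matrix `ni` (`n_perm x p`) of
#'   per-run permuted NI values, plus `mse`, `corr`, `seeds`.
#' @export
ert_perm_null <- function(X, y, n_perm = 100L, train_frac = 0.9,
                          n_trees = 50L, bootstrap = TRUE,
                          mtry_fraction = 1 / 3, min_leaf = 5L,
                          max_surrogates = 10L, stratify = NULL,
                          seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y have mismatched lengths")
  p <- ncol(X)
  mtry <- max(1L, as.integer(round(mtry_fraction * p)))
  ni <- matrix(NA_real_, n_perm, p, dimnames = list(NULL, colnames(X)))
  mse <- corr <- numeric(n_perm)
  seeds <- integer(n_perm)
  n_zero <- 0L
  for (i in seq_len(n_perm)) {
    yp <- .with_seed(.derive_seed(seed, i, 3L), y[sample.int(n)])
    seeds[i] <- .derive_seed(seed, i, 4L)
    train_idx <- .with_seed(seeds[i],
                            .draw_train(n, train_frac, stratify))
    r <- .fit_eval_once(X, yp, train_idx, as.integer(n_trees),
                        isTRUE(bootstrap), mtry, as.integer(min_leaf),
                        as.integer(max_surrogates),
                        .derive_seed(seed, i, 5L))
    mse[i] <- r$mse
    corr[i] <- r$corr
    if (any(r$importance > 0)) {
      s <- sqrt(r$importance)
      ni[i, ] <- s / mean(s)
    } else {
      n_zero <- n_zero + 1L
    }
  }
  if (n_zero > 0)
    message(n_zero, " permutation run(s) recorded no splits; NA NI rows")
  structure(
    list(ni = ni, mse = mse, corr = corr, seeds = seeds,
         n_perm = as.integer(n_perm), train_frac = train_frac,
         n = n, p = p, n_zero_importance = n_zero, shuffled = TRUE),
    class = "ert_permnull"
  )
}

#' @export
print.ert_permnull <- function(x, ...) {
  cat(sprintf("ert_permnull: %d label-shuffled runs, %d regions\n",
              x$n_perm, x$p))
  cat(sprintf("  pooled permuted NI %.3f +/- %.3f\n",
              mean(x$ni, na.rm = TRUE), stats::sd(x$ni, na.rm = TRUE)))
  invisible(x)
}
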