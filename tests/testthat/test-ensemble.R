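# Ensembles: recomposition from trees, determinism, variance reduction.

test_that("a degenerate ensemble equals a single tree", {
  d <- tiny_data(21, n = 30, p = 3)
  e <- ert(d$X, d$y, n_trees = 1, bootstrap = FALSE,
           mtry_fraction = 1, min_leaf = 3, seed = 5)
  t1 <- ert_tree(d$X, d$y, min_leaf = 3, seed = 5)
  expect_equal(predict(e, d$X), predict(t1, d$X))
  expect_equal(importance(e), importance(t1))
})

test_that("constant response gives single-leaf trees predicting the "
          %+% "constant", {
  X <- matrix(rnorm(60), 20)
  e <- ert(X, rep(3, 20), n_trees = 5, min_leaf = 2, seed = 1)
  expect_equal(predict(e, X), rep(3, 20))
  expect_equal(unname(importance(e)), rep(0, 3))
})

test_that("ensemble prediction and importance recompose from the "
          %+% "individual trees", {
  d <- tiny_data(22, n = 40, p = 4)
  e <- ert(d$X, d$y, n_trees = 7, min_leaf = 3, seed = 2)
  per_tree_pred <- vapply(e$trees, predict, numeric(40), newdata = d$X)
  expect_equal(predict(e, d$X), rowMeans(per_tree_pred))
  per_tree_imp <- vapply(e$trees, importance, numeric(4))
  expect_equal(unname(importance(e)), unname(rowMeans(per_tree_imp)),
               tolerance = 1e-12)
  # and per-tree importance agrees with the pure-R recomputation
  for (tr in e$trees)
    expect_equal(recompute_importance(tr), importance(tr),
                 tolerance = 1e-12)
})

test_that("identical seeds give bit-identical ensembles", {
  d <- tiny_data(23, n = 30, p = 3)
  e1 <- ert(d$X, d$y, n_trees = 4, seed = 11)
  e2 <- ert(d$X, d$y, n_trees = 4, seed = 11)
  expect_identical(importance(e1), importance(e2))
  expect_identical(predict(e1, d$X), predict(e2, d$X))
  e3 <- ert(d$X, d$y, n_trees = 4, seed = 12)
  expect_false(identical(importance(e1), importance(e3)))
})

test_that("risk conservation holds in every ensemble member", {
  d <- tiny_data(24, n = 50, p = 4)
  e <- ert(d$X, d$y, n_trees = 10, min_leaf = 3, seed = 3)
  for (tr in e$trees) {
    expect_risk_conservation(tr)
    expect_true(all(importance(tr) >= 0))
  }
})

test_that("the formula interface matches the matrix interface", {
  d <- tiny_data(25, n = 30, p = 3)
  df <- data.frame(y = d$y, d$X)
  ef <- ert(y ~ ., data = df, n_trees = 3, seed = 4)
  em <- ert(d$X, d$y, n_trees = 3, seed = 4)
  expect_equal(unname(importance(ef)), unname(importance(em)))
})

test_that("bagging reduces held-out error relative to a single tree", {
  # same tree settings on both sides: 50 bagged trees vs one tree on the
  # full sample
  mse_bag <- mse_one <- numeric(20)
  for (seed in 1:20) {
    set.seed(3000 + seed)
    n <- 150
    X <- matrix(rnorm(n * 10), n)
    y <- X[, 1] - 0.8 * X[, 2] + rnorm(n, sd = 0.5)
    tr_idx <- sample(n, 120)
    Xtr <- X[tr_idx, ]; ytr <- y[tr_idx]
    Xte <- X[-tr_idx, ]; yte <- y[-tr_idx]
    e <- ert(Xtr, ytr, n_trees = 50, mtry_fraction = 1, seed = seed)
    t1 <- ert(Xtr, ytr, n_trees = 1, bootstrap = FALSE,
              mtry_fraction = 1, seed = seed)
    mse_bag[seed] <- mean((predict(e, Xte) - yte)^2)
    mse_one[seed] <- mean((predict(t1, Xte) - yte)^2)
  }
  expect_gte(sum(mse_bag <= mse_one), 15L)
  expect_lt(mean(mse_bag), mean(mse_one))
})

test_that("an appended pure-noise feature earns less importance than "
          %+% "every informative feature", {
  co <- make_fixture("planted", seed = 500)
  sel <- select_group(co, "HC_AD", "panelA", "MMSE")
  imp_noise <- imp_planted_min <- numeric(20)
  for (seed in 1:20) {
    set.seed(4000 + seed)
    Xa <- cbind(sel$X, noise = rnorm(nrow(sel$X)))
    e <- ert(Xa, sel$y, n_trees = 20, seed = seed, keep_trees = FALSE)
    imp <- importance(e)
    imp_noise[seed] <- imp["noise"]
    imp_planted_min[seed] <- min(imp[1:3])
  }
  expect_lt(mean(imp_noise), min(imp_planted_min))
})

test_that("invalid ensemble configurations are rejected", {
  d <- tiny_data(26, n = 12, p = 2)
  expect_error(ert(d$X, d$y, mtry_fraction = 0), "mtry_fraction")
  expect_error(ert(d$X, d$y[-1]), "mismatch")
  expect_error(ert(d$X[1:4, ], d$y[1:4], min_leaf = 5), "min_leaf")
  e <- ert(d$X, d$y, n_trees = 2, min_leaf = 2, keep_trees = FALSE)
  expect_error(predict(e, d$X), "keep_trees")
})
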