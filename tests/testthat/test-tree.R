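# Single surrogate-split regression trees: split choice, surrogates,
# node-risk accounting and importance.

test_that("a perfectly separable step function splits at the gap", {
  x <- matrix(0:3, ncol = 1)
  y <- c(0, 0, 10, 10)
  fit <- ert_tree(x, y, min_leaf = 1)
  expect_equal(fit$nodes$threshold[1], 1.5)
  # total reduction equals root risk = population variance of y
  expect_equal(fit$nodes$risk_reduction[1], 25)
  expect_equal(fit$nodes$risk[1], 25)
  leaves <- is.na(fit$nodes$feature)
  expect_true(all(fit$nodes$mse[leaves] == 0))
  # routing follows the stored threshold
  expect_equal(predict(fit, matrix(1.5)), 10)
  expect_equal(predict(fit, matrix(1.4)), 0)
  expect_equal(importance(fit), c(X1 = 25))
})

test_that("constant response yields a single leaf with zero risk", {
  fit <- ert_tree(matrix(rnorm(8), 4), rep(5, 4), min_leaf = 1)
  expect_equal(nrow(fit$nodes), 1L)
  expect_equal(fit$n_branch_nodes, 0L)
  expect_equal(fit$nodes$prediction[1], 5)
  expect_equal(fit$nodes$risk[1], 0)
  expect_equal(unname(importance(fit)), rep(0, fit$feature_count))
  expect_equal(predict(fit, matrix(rnorm(6), 3)), rep(5, 3))
})

test_that("fitted splits, surrogates and importance match exhaustive "
          %+% "brute force on tiny problems", {
  for (seed in c(1, 2, 7, 11)) {
    for (min_leaf in c(1L, 2L, 3L)) {
      d <- tiny_data(seed)
      fit <- ert_tree(d$X, d$y, min_leaf = min_leaf)
      otree <- oracle_tree(d$X, d$y, min_leaf)
      expect_tree_matches_oracle(fit, otree)
      expect_equal(unname(importance(fit)),
                   oracle_importance(otree, ncol(d$X)),
                   tolerance = 1e-12)
    }
  }
})

test_that("a duplicated column becomes a perfect surrogate", {
  set.seed(3)
  x1 <- rnorm(12)
  y <- 2 * x1 + rnorm(12, sd = 0.1)
  X <- cbind(x1, x1, rnorm(12))
  fit <- ert_tree(X, y, min_leaf = 2)
  expect_equal(fit$nodes$feature[1], 1L)  # tie broken to lowest index
  s <- fit$surrogates[[1]]
  dup <- s[s$feature == 2L, ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$association, 1)
  expect_equal(dup$risk_reduction, fit$nodes$risk_reduction[1])
  # both copies receive identical positive importance
  imp <- importance(fit)
  expect_gt(imp[1], 0)
  expect_equal(unname(imp[1]), unname(imp[2]))
})

test_that("features that cannot beat majority routing are not surrogates", {
  # constant feature: any threshold routes everything one way ->
  # agreement equals the majority fraction -> lambda <= 0 -> excluded
  set.seed(4)
  X <- cbind(rnorm(20), rep(1, 20))
  y <- X[, 1] + rnorm(20, sd = 0.1)
  fit <- ert_tree(X, y, min_leaf = 2)
  for (s in fit$surrogates) expect_false(2L %in% s$feature)
})

test_that("memorizing trees reproduce training responses exactly", {
  d <- tiny_data(5, n = 10, p = 2)
  # distinct y values and min_leaf = 1 allow pure leaves
  fit <- ert_tree(d$X, d$y, min_leaf = 1)
  expect_equal(predict(fit, d$X), d$y)
})

test_that("risk accounting is conserved and children partition parents", {
  for (seed in 1:3) {
    d <- tiny_data(seed, n = 30, p = 4)
    fit <- ert_tree(d$X, d$y, min_leaf = 3)
    expect_risk_conservation(fit)
    nd <- fit$nodes
    for (i in which(!is.na(nd$feature))) {
      expect_equal(nd$probability[nd$left[i]] +
                     nd$probability[nd$right[i]],
                   nd$probability[i])
      expect_equal(nd$risk[i], nd$probability[i] * nd$mse[i])
    }
    expect_true(all(importance(fit) >= 0))
    expect_equal(fit$n_branch_nodes, sum(!is.na(nd$feature)))
  }
})

test_that("permuting feature columns permutes importance identically", {
  d <- tiny_data(9, n = 24, p = 4)
  perm <- c(3L, 1L, 4L, 2L)
  f1 <- ert_tree(d$X, d$y, min_leaf = 2)
  f2 <- ert_tree(d$X[, perm], d$y, min_leaf = 2)
  expect_equal(unname(importance(f2)),
               unname(importance(f1))[perm], tolerance = 1e-12)
})

test_that("a positive affine transform of one feature leaves the "
          %+% "partition unchanged", {
  d <- tiny_data(10, n = 24, p = 3)
  X2 <- d$X
  X2[, 2] <- 5 * X2[, 2] - 7
  f1 <- ert_tree(d$X, d$y, min_leaf = 2)
  f2 <- ert_tree(X2, d$y, min_leaf = 2)
  expect_equal(f1$nodes$n, f2$nodes$n)
  expect_equal(f1$nodes$feature, f2$nodes$feature)
  expect_equal(predict(f1, d$X), predict(f2, X2))
})

test_that("importance recomputed in R from the serialized tree matches, "
          %+% "including after a JSON round trip", {
  d <- tiny_data(12, n = 20, p = 3)
  fit <- ert_tree(d$X, d$y, min_leaf = 2)
  expect_equal(recompute_importance(fit), importance(fit),
               tolerance = 1e-12)
  path <- tempfile(fileext = ".json")
  write_ert_tree(fit, path)
  back <- read_ert_tree(path)
  expect_equal(recompute_importance(back), importance(fit),
               tolerance = 1e-12)
  expect_equal(predict(back, d$X), predict(fit, d$X))
})

test_that("mismatched dimensions are rejected", {
  expect_error(ert_tree(matrix(1:6, 3), 1:2), "mismatch")
  fit <- ert_tree(matrix(rnorm(12), 6), rnorm(6), min_leaf = 1)
  expect_error(predict(fit, matrix(1, 1, 3)), "columns")
})
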