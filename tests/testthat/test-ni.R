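# Normalized importance, threshold, ranking, standardization, consensus.

test_that("NI follows the stated square-root mean-one arithmetic", {
  # mean importances [4, 1] -> sqrt [2, 1] -> ni [4/3, 2/3]
  imp <- rbind(c(4, 1), c(4, 1))
  expect_equal(unname(compute_ni(imp)), c(4 / 3, 2 / 3))
  # identical columns -> all ones
  expect_equal(unname(compute_ni(matrix(2, 5, 4))), rep(1, 4))
})

test_that("NI has mean one and is scale invariant", {
  set.seed(5)
  for (k in 1:10) {
    imp <- matrix(rexp(60), 10, 6)
    ni <- compute_ni(imp)
    expect_equal(mean(ni), 1, tolerance = 1e-12)
    expect_equal(compute_ni(imp * 37.5), ni, tolerance = 1e-12)
  }
})

test_that("all-zero importance is an error", {
  expect_error(compute_ni(matrix(0, 5, 3)), "no splits")
})

test_that("the pooled threshold is mean plus two sample SDs", {
  expect_equal(ni_threshold(matrix(1, 4, 3)), 1)  # degenerate -> mean
  # pooled values {0, 2} equally: mean 1, SD 1 -> threshold 3
  perm <- rbind(c(0, 2), c(2, 0))
  v <- as.numeric(perm)
  expect_equal(ni_threshold(perm), mean(v) + 2 * sd(v))
  expect_equal(ni_threshold(perm), 1 + 2 * sd(c(0, 2, 2, 0)))
  # per-region variant
  thr <- ni_threshold(rbind(c(0, 1), c(2, 1)), type = "per_region")
  expect_equal(unname(thr), c(1 + 2 * sd(c(0, 2)), 1))
})

test_that("flagging is strict and ranking breaks ties by index", {
  fr <- flag_and_rank(c(1.5, 0.9, 1.2), 1.1)
  expect_equal(fr$significant, c(TRUE, FALSE, TRUE))
  expect_equal(fr$rank_order, c(1L, 3L, 2L))
  # ties at the threshold are not significant
  expect_equal(flag_and_rank(c(1.1, 1.2), 1.1)$significant,
               c(FALSE, TRUE))
  # a threshold above max(ni) flags nothing
  expect_equal(sum(flag_and_rank(c(1.5, 0.9), 2)$significant), 0)
  # ties in ni rank by ascending index
  expect_equal(flag_and_rank(c(1, 1, 2), 0)$rank_order, c(3L, 1L, 2L))
})

make_profile <- function(ni, thr, bm = "panelA", gr = "HC_AD",
                         tg = "MMSE") {
  fr <- flag_and_rank(ni, thr)
  structure(list(ni = ni, threshold = thr, significant = fr$significant,
                 rank_order = fr$rank_order,
                 region_names = paste0("R", seq_along(ni)),
                 biomarker = bm, group = gr, target = tg),
            class = "ni_profile")
}

test_that("cross-group standardization is a pooled min-max onto [0, 1] "
          %+% "preserving within-group order", {
  set.seed(8)
  profs <- lapply(c("HC_MCI", "HC_AD", "MCI_AD", "HC_MCI_AD"),
                  function(g) make_profile(runif(6, 0.5, 2), 1.2,
                                           gr = g))
  m <- standardize_across_groups(profs)
  expect_equal(dim(m), c(4L, 6L))
  expect_equal(min(m), 0)
  expect_equal(max(m), 1)
  for (i in 1:4)
    expect_equal(order(-m[i, ]), order(-profs[[i]]$ni))
  # identical profiles give identical rows
  same <- standardize_across_groups(lapply(1:4, function(i)
    make_profile(c(1, 2, 0.5), 1)))
  expect_true(all(apply(same, 2, function(col) diff(range(col)) == 0)))
})

test_that("consensus counts significant flags across the three scores", {
  p1 <- make_profile(c(2.0, 1.5, 0.8), 1.2, tg = "MMSE")
  p2 <- make_profile(c(1.9, 0.9, 0.7), 1.2, tg = "CDRSB")
  p3 <- make_profile(c(1.8, 1.4, 0.6), 1.2, tg = "ADAS")
  cm <- consensus(list(p1, p2, p3))
  expect_equal(cm$consensus, c(3L, 2L, 0L))
  expect_named(cm, c("region", "consensus", "ni_mmse", "ni_cdrsb",
                     "ni_adas"))
  # no significant flags anywhere -> all zeros
  z <- consensus(lapply(c("MMSE", "CDRSB", "ADAS"), function(tg)
    make_profile(c(0.9, 1.0, 1.1), 2, tg = tg)))
  expect_equal(z$consensus, c(0L, 0L, 0L))
  # mixing groups is rejected
  expect_error(consensus(list(p1, p2, make_profile(c(1, 1, 1), 1,
                                                   gr = "HC_MCI"))),
               "mix")
})

test_that("lowering the threshold never decreases consensus", {
  set.seed(11)
  ni <- replicate(3, runif(8, 0.5, 2), simplify = FALSE)
  for (pair in list(c(1.5, 1.2), c(1.2, 0.9))) {
    hi <- consensus(lapply(seq_along(.targets <- c("MMSE", "CDRSB",
                                                   "ADAS")),
                           function(i) make_profile(ni[[i]], pair[1],
                                                    tg = .targets[i])))
    lo <- consensus(lapply(seq_along(.targets),
                           function(i) make_profile(ni[[i]], pair[2],
                                                    tg = .targets[i])))
    expect_true(all(lo$consensus >= hi$consensus))
  }
})

test_that("consensus maps round trip through CSV", {
  p <- lapply(c("MMSE", "CDRSB", "ADAS"), function(tg)
    make_profile(c(2, 0.8, 1.4), 1.2, tg = tg))
  cm <- consensus(p)
  f <- tempfile(fileext = ".csv")
  write_consensus(cm, f)
  back <- read.csv(f)
  expect_equal(back$consensus, cm$consensus)
  expect_equal(back$ni_mmse, cm$ni_mmse)
})
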