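# Cohort statistics: ANOVA from summaries and raw data, chi-squared,
# Tukey HSD, correlation summaries.

test_that("summary-based ANOVA reproduces published demographic F "
          %+% "statistics", {
  a <- anova_from_summaries(c(265, 274, 227), c(29.06, 27.63, 23.08),
                            c(1.18, 1.89, 2.67))
  expect_equal(a$f, 604.83, tolerance = 0.5 / 100)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 763L)
  expect_lt(a$p, 1e-4)
})

test_that("identical groups give F = 0 with p = 1", {
  a <- anova_from_summaries(c(10, 10), c(5, 5), c(1, 1))
  expect_equal(a$f, 0)
  expect_equal(a$p, 1)
})

test_that("for two groups F equals the squared pooled-variance t "
          %+% "statistic", {
  n <- c(14, 20); m <- c(3.1, 2.4); s <- c(1.2, 0.9)
  a <- anova_from_summaries(n, m, s)
  sp2 <- sum((n - 1) * s^2) / (sum(n) - 2)
  tstat <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  expect_equal(a$f, tstat^2, tolerance = 1e-12)
})

test_that("raw-data ANOVA agrees with the summary route", {
  set.seed(6)
  for (k in 1:5) {
    g <- rep(1:3, times = c(8, 12, 10))
    v <- rnorm(30, mean = g)
    a_raw <- anova_oneway(v, g)
    st <- vapply(split(v, g), function(x) c(length(x), mean(x), sd(x)),
                 numeric(3))
    a_sum <- anova_from_summaries(st[1, ], st[2, ], st[3, ])
    expect_equal(a_raw$f, a_sum$f, tolerance = 1e-9)
    expect_equal(a_raw$p, a_sum$p, tolerance = 1e-9)
  }
  expect_equal(anova_oneway(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$f, 0)
})

test_that("ANOVA separates resampled MSE vectors when one biomarker "
          %+% "carries signal and the other does not", {
  co <- make_fixture("planted", seed = 31)
  sA <- select_group(co, "HC_AD", "panelA", "MMSE")  # planted signal
  sB <- select_group(co, "HC_AD", "panelB", "MMSE")  # pure noise panel
  rA <- ert_resample(sA$X, sA$y, n_iter = 30, seed = 1)
  rB <- ert_resample(sB$X, sB$y, n_iter = 30, seed = 2)
  a <- anova_oneway(c(rA$mse, rB$mse), rep(c("A", "B"), each = 30))
  expect_lt(a$p, 0.01)
  expect_lt(mean(rA$mse), mean(rB$mse))
})

test_that("chi-squared reproduces the published sex-by-diagnosis "
          %+% "statistics and the direct formula", {
  expect_equal(chi_squared(rbind(c(124, 160, 122),
                                 c(141, 114, 105)))$x2, 7.35,
               tolerance = 0.001)
  # 2x2 by hand: margins 30/30, expected 15 everywhere
  res <- chi_squared(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$x2, 4 * 25 / 15)
  expect_equal(res$df, 1)
  # proportional rows -> 0
  expect_equal(chi_squared(rbind(c(10, 20, 30), c(20, 40, 60)))$x2, 0)
  # invariant to column permutation
  tab <- rbind(c(12, 7, 30), c(8, 20, 14))
  expect_equal(chi_squared(tab)$x2, chi_squared(tab[, c(3, 1, 2)])$x2)
  expect_error(chi_squared(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Tukey HSD flags match an independent studentized-range "
          %+% "computation", {
  set.seed(12)
  samples <- list(a = rnorm(40, 0), b = rnorm(40, 0.4),
                  c = rnorm(40, 2))
  res <- suppressMessages(tukey_hsd(samples, fwer = 0.01))
  # independent route: Tukey-Kramer with qtukey
  v <- unlist(samples)
  g <- rep(names(samples), each = 40)
  msw <- sum(vapply(split(v, g), function(x)
    sum((x - mean(x))^2), 1)) / (length(v) - 3)
  qc <- qtukey(0.99, 3, length(v) - 3)
  for (i in seq_len(nrow(res))) {
    pp <- strsplit(res$pair[i], "-")[[1]]
    diffm <- abs(mean(samples[[pp[1]]]) - mean(samples[[pp[2]]]))
    se <- sqrt(msw / 2 * (1 / 40 + 1 / 40))
    expect_equal(unname(res$significant[i]), diffm / se > qc)
  }
})

test_that("Tukey flags are a subset of unadjusted pairwise-t flags", {
  set.seed(13)
  samples <- list(a = rnorm(30, 0), b = rnorm(30, 0.5),
                  c = rnorm(30, 0.8), d = rnorm(30, 1.5))
  alpha <- 0.05
  res <- suppressMessages(tukey_hsd(samples, fwer = alpha))
  for (i in seq_len(nrow(res))) {
    pp <- strsplit(res$pair[i], "-")[[1]]
    p_t <- t.test(samples[[pp[1]]], samples[[pp[2]]],
                  var.equal = TRUE)$p.value
    if (res$significant[i]) expect_lt(p_t, alpha)
  }
})

test_that("identical samples are never flagged and one shifted "
          %+% "biomarker is flagged against all others", {
  res <- suppressMessages(
    tukey_hsd(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  )
  expect_equal(res$diff, 0)
  expect_false(res$significant)
  flagged <- 0L
  for (seed in 1:20) {
    set.seed(5000 + seed)
    samples <- lapply(1:9, function(i) rnorm(100, 0, 1))
    names(samples) <- paste0("b", 1:9)
    samples$b5 <- samples$b5 + 5
    res <- suppressMessages(tukey_hsd(samples, fwer = 0.01))
    hit <- grepl("b5", res$pair)
    if (all(res$significant[hit])) flagged <- flagged + 1L
  }
  expect_gte(flagged, 18L)
})

test_that("correlation summaries handle constants, sign balance and "
          %+% "undefined entries", {
  s <- correlation_summary(rep(0.5, 10))
  expect_equal(s$mean_r, 0.5)
  expect_equal(s$sd_r, 0)
  expect_equal(s$n_defined, 10L)
  s2 <- correlation_summary(c(1, -1))
  expect_equal(s2$mean_r, 0)
  s3 <- correlation_summary(c(0.2, NA, 0.4))
  expect_equal(s3$n_undefined, 1L)
  expect_equal(s3$mean_r, 0.3)
})
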