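# Cohort-level statistics: one-way ANOVA (from raw data or from printed
# per-group summaries), chi-squared tests for categorical tables, Tukey HSD
# across biomarkers at a family-wise error rate, and correlation summaries.

#' One-way ANOVA reconstructed from per-group summaries
#'
#' Computes the classical one-way F statistic from per-group (n, mean, SD)
#' triplets - the form in which demographic tables print them - using
#' SSB = sum n_i (mean_i - grand)^2 and SSW = sum (n_i - 1) sd_i^2.
#' Equivalent to [anova_oneway()] on the underlying raw data.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group SDs (sample SD, n-1).
#' @return List of class `ertni_anova` with `f`, `df_between`,
#'   `df_within`, `p`.
#' @examples
#' # MMSE by diagnosis from printed summaries:
#' anova_from_summaries(c(265, 274, 227), c(29.06, 27.63, 23.08),
#'                      c(1.18, 1.89, 2.67))
#' @export
anova_from_summaries <- function(n, mean, sd) {
  k <- length(n)
  if (k < 2 || length(mean) != k || length(sd) != k)
    stop("need aligned n, mean, sd for at least two groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sd < 0)) stop("negative SD")
  N <- sum(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  dfb <- k - 1L
  dfw <- N - k
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / dfb) / (ssw / dfw)
  }
  structure(list(f = f, df_between = dfb, df_within = as.integer(dfw),
                 p = stats::pf(f, dfb, dfw, lower.tail = FALSE)),
            class = "ertni_anova")
}

#' One-way ANOVA on raw data
#'
#' Classical equal-variance one-way ANOVA; agrees with
#' [anova_from_summaries()] applied to the per-group (n, mean, sd) of the
#' same data.
#'
#' @param values Numeric vector.
#' @param labels Grouping vector of the same length.
#' @return List of class `ertni_anova` with `f`, `df_between`,
#'   `df_within`, `p`.
#' @export
anova_oneway <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("every group needs n >= 2")
  ft <- oneway.test(values ~ labels, var.equal = TRUE)
  structure(list(f = unname(ft$statistic),
                 df_between = as.integer(ft$parameter[["num df"]]),
                 df_within = as.integer(ft$parameter[["denom df"]]),
                 p = unname(ft$p.value)),
            class = "ertni_anova")
}

#' @export
print.ertni_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Pearson chi-squared test for a count table
#'
#' Uncorrected (no Yates continuity correction) chi-squared with expected
#' counts from the margins.
#'
#' @param table Integer matrix of counts (e.g. 2 x k sex-by-diagnosis).
#' @return List with `x2`, `df`, `p`.
#' @examples
#' chi_squared(rbind(male = c(124, 160, 122), female = c(141, 114, 105)))
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(x2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Tukey HSD comparison across biomarkers
#'
#' All pairwise mean differences between the supplied per-biomarker
#' vectors (typically per-iteration test MSEs), tested against the
#' studentized-range distribution with pooled within-group variance and
#' the Tukey-Kramer unequal-n adjustment, at family-wise error rate
#' `fwer`.
#'
#' When the vectors are per-iteration results that share subjects across
#' iterations, the observations are not independent; a message notes this.
#'
#' @param samples Named list of numeric vectors, one per biomarker.
#' @param fwer Family-wise error rate (default 0.01).
#' @param warn_dependence Message about across-iteration dependence
#'   (default TRUE).
#' @return data.frame with one row per pair: `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant` (interval excludes zero at level
#'   `1 - fwer`).
#' @export
tukey_hsd <- function(samples, fwer = 0.01, warn_dependence = TRUE) {
  if (length(samples) < 2) stop("need at least two biomarkers")
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list")
  if (any(vapply(samples, length, 1L) < 2))
    stop("every sample needs at least two values")
  if (warn_dependence)
    message("tukey_hsd: values sharing subjects across iterations are ",
            "dependent; p-values are approximate")
  df <- data.frame(
    value = unlist(samples, use.names = FALSE),
    biomarker = factor(rep(names(samples),
                           vapply(samples, length, 1L)),
                       levels = names(samples))
  )
  fit <- aov(value ~ biomarker, data = df)
  tk <- TukeyHSD(fit, conf.level = 1 - fwer)$biomarker
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    significant = tk[, "lwr"] > 0 | tk[, "upr"] < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Mean and SD of test-set correlations
#'
#' Summarises the per-iteration predicted-vs-actual Pearson correlations
#' of an [ert_resample()] result, over iterations where the correlation is
#' defined.
#'
#' @param results An `ert_resample` object or numeric correlation vector
#'   (may contain `NA`).
#' @return List with `mean_r`, `sd_r`, `n_defined`, `n_undefined`.
#' @export
correlation_summary <- function(results) {
  r <- if (inherits(results, "ert_resample")) results$corr else
    as.numeric(results)
  ok <- !is.na(r)
  list(mean_r = if (any(ok)) mean(r[ok]) else NA_real_,
       sd_r = if (sum(ok) > 1) stats::sd(r[ok]) else 0,
       n_defined = sum(ok), n_undefined = sum(!ok))
}
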