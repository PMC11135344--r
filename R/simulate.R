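# Synthetic ADNI-like cohort generator.  Scores are drawn per (diagnosis,
# target) from truncated normals with the published per-group means/SDs;
# biomarker values are region baselines plus optional linear effects in the
# standardized scores, active only in configured diagnoses, plus Gaussian
# noise.

.default_score_params <- list(
  HC  = list(MMSE = c(29.06, 1.18), CDRSB = c(0.04, 0.14),
             ADAS = c(8.61, 4.06)),
  MCI = list(MMSE = c(27.63, 1.89), CDRSB = c(1.28, 0.74),
             ADAS = c(15.01, 6.22)),
  AD  = list(MMSE = c(23.08, 2.67), CDRSB = c(4.48, 1.80),
             ADAS = c(29.23, 8.20))
)
.default_age_params <- list(HC = c(73.91, 5.57), MCI = c(73.48, 7.38),
                            AD = c(74.43, 7.97))
.default_sex_probs <- c(HC = 124 / 265, MCI = 160 / 274, AD = 122 / 227)
.default_n <- c(HC = 265L, MCI = 274L, AD = 227L)

#' Specify a planted region-score effect
#'
#' Declares that one region of one biomarker varies linearly with the
#' standardized value of one cognitive score, in the configured diagnoses
#' only.  Sign is free: atrophy-like measures fall with worsening scores,
#' diffusivity- and amyloid-like measures rise.
#'
#' @param biomarker Biomarker name.
#' @param region Region index (1-based) within that biomarker.
#' @param target `"MMSE"`, `"CDRSB"` or `"ADAS"`.
#' @param slope Effect size, feature units per SD of score.
#' @param active Diagnoses in which the effect operates (default `"AD"`).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(biomarker, region, target, slope, active = "AD") {
  stopifnot(is.finite(slope), region >= 1,
            all(active %in% .diagnoses), target %in% .targets)
  structure(list(biomarker = biomarker, region = as.integer(region),
                 target = target, slope = slope, active = active),
            class = "effect_spec")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published sMRI subsample: group sizes 265/274/227
#' (HC/MCI/AD), the per-group score means and SDs, per-group male
#' probabilities, and the nine canonical biomarker panels.  Region baselines
#' default to mean 1.0 with SD 0.1 across regions, in arbitrary units: the
#' tree pipeline is per-feature scale-equivariant, so absolute units are
#' immaterial.
#'
#' @param n_per_group Named integer vector `c(HC=, MCI=, AD=)`.
#' @param score_params Nested list `[[diagnosis]][[target]] = c(mean, sd)`.
#' @param age_params List `[[diagnosis]] = c(mean, sd)` in years.
#' @param sex_probs Named vector of P(male) per diagnosis.
#' @param biomarkers Named integer vector, biomarker -> region count.
#' @param baseline_mean,baseline_sd Mean and SD of region baseline levels.
#' @param noise_sd Residual SD of each biomarker value (single number or
#'   named per-biomarker vector).
#' @param effects List of [effect_spec()] objects.
#' @param seed Integer seed; the generated cohort is a deterministic
#'   function of the full configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = .default_n,
                       score_params = .default_score_params,
                       age_params = .default_age_params,
                       sex_probs = .default_sex_probs,
                       biomarkers = canonical_biomarkers(),
                       baseline_mean = 1.0, baseline_sd = 0.1,
                       noise_sd = 0.1, effects = list(), seed = 1L) {
  stopifnot(all(n_per_group >= 0), all(sex_probs >= 0 & sex_probs <= 1),
            baseline_sd > 0 || baseline_sd == 0, all(noise_sd >= 0),
            all(biomarkers >= 1))
  for (dx in .diagnoses)
    for (tg in .targets)
      stopifnot(length(score_params[[dx]][[tg]]) == 2,
                score_params[[dx]][[tg]][2] > 0)
  if (length(noise_sd) == 1 && is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep(noise_sd, length(biomarkers)),
                                names(biomarkers))
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (!e$biomarker %in% names(biomarkers))
      stop("effect references unknown biomarker ", e$biomarker)
    if (e$region > biomarkers[[e$biomarker]])
      stop("effect region index exceeds ", e$biomarker, " region count")
  }
  structure(list(n_per_group = n_per_group, score_params = score_params,
                 age_params = age_params, sex_probs = sex_probs,
                 biomarkers = biomarkers, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 effects = effects, seed = as.integer(seed)),
            class = "sim_config")
}

# mean of clip(N(m, s), a, b); infinite bounds handled
.clip_mean <- function(m, s, a, b) {
  al <- (a - m) / s
  be <- (b - m) / s
  aterm <- if (is.finite(a)) a * stats::pnorm(al) else 0
  bterm <- if (is.finite(b)) b * stats::pnorm(be, lower.tail = FALSE) else 0
  aterm + bterm + m * (stats::pnorm(be) - stats::pnorm(al)) -
    s * (stats::dnorm(be) - stats::dnorm(al))
}

# truncated normal honouring hard score bounds: draw from a mean-shifted
# normal, redraw beyond 4 SD, clip to range.  The shift is solved so the
# clipped draw has expectation `mean` - clipping alone would bias group
# means near a bound (e.g. a mean 1 SD below the score ceiling) by more
# than a standard error at realistic group sizes.
.rtrunc <- function(n, mean, sd, lo, hi) {
  delta <- 0
  if ((is.finite(lo) || is.finite(hi)) &&
      abs(.clip_mean(mean, sd, lo, hi) - mean) > 1e-12) {
    delta <- stats::uniroot(
      function(d) .clip_mean(mean + d, sd, lo, hi) - mean,
      interval = c(-4 * sd, 4 * sd), extendInt = "yes", tol = 1e-10
    )$root
  }
  x <- rnorm(n, mean + delta, sd)
  for (k in 1:20) {
    out <- abs(x - (mean + delta)) > 4 * sd
    if (!any(out)) break
    x[out] <- rnorm(sum(out), mean + delta, sd)
  }
  pmin(hi, pmax(lo, x))
}

#' Simulate an ADNI-like cohort
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An `ert_cohort`; identical seed and config give a bit-identical
#'   cohort.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  dx <- rep(.diagnoses, times = config$n_per_group[.diagnoses])
  n <- length(dx)
  if (n == 0) stop("empty cohort: all group sizes are zero")
  ids <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_probs[dx], "M", "F")
  age <- numeric(n)
  scores <- matrix(0, n, 3, dimnames = list(NULL, .targets))
  for (d in .diagnoses) {
    sel <- dx == d
    if (!any(sel)) next
    ap <- config$age_params[[d]]
    age[sel] <- pmax(1, .rtrunc(sum(sel), ap[1], ap[2], 1, Inf))
    for (tg in .targets) {
      sp <- config$score_params[[d]][[tg]]
      rg <- .score_ranges[[tg]]
      scores[sel, tg] <- .rtrunc(sum(sel), sp[1], sp[2], rg[1], rg[2])
    }
  }
  subjects <- data.frame(subject_id = ids, diagnosis = dx, sex = sex,
                         age = age, mmse = scores[, "MMSE"],
                         cdrsb = scores[, "CDRSB"], adas = scores[, "ADAS"],
                         stringsAsFactors = FALSE)

  # standardized scores over the full cohort (effects are linear in these)
  z <- scale(scores)
  if (n == 1) z[] <- 0

  mats <- list()
  for (bm in names(config$biomarkers)) {
    p <- config$biomarkers[[bm]]
    mu <- rnorm(p, config$baseline_mean, config$baseline_sd)
    vals <- matrix(rep(mu, each = n), n, p) +
      matrix(rnorm(n * p, 0, config$noise_sd[[bm]]), n, p)
    for (e in config$effects) {
      if (e$biomarker != bm) next
      act <- dx %in% e$active
      vals[, e$region] <- vals[, e$region] +
        e$slope * z[, e$target] * act
    }
    colnames(vals) <- paste0(bm, "_R", seq_len(p))
    if (p == 68L) colnames(vals) <- dk_regions()
    mats[[bm]] <- biomarker_matrix(bm, vals, ids)
  }
  cohort(subjects, mats)
}

# Planted-effect slope for the recovery fixture: with noise SD 0.1 and the
# default score distributions, a slope of 0.03 per SD on each of the three
# standardized scores gives a planted-region univariate R^2 of about 0.2
# against each score within the HC/AD selection (effects active in AD only).
.planted_slope <- 0.03

#' Built-in synthetic fixtures
#'
#' * `tiny` - 12 subjects (4 per diagnosis), two 4-region panels; small
#'   enough for exhaustive-oracle tests.
#' * `paper_like` - published sMRI group sizes and score distributions, all
#'   nine canonical biomarker panels, no planted effects.
#' * `planted` - desk-scale recovery fixture: 100 subjects per diagnosis,
#'   panelA (30 regions, regions 1-3 associated with all three scores in AD
#'   subjects only, slope 0.03 per score SD) and panelB (20 null regions).
#'
#' @param name Fixture name.
#' @param seed Integer seed (default 101).
#' @return An `ert_cohort`.
#' @export
make_fixture <- function(name = c("tiny", "paper_like", "planted"),
                         seed = 101L) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    tiny = sim_config(
      n_per_group = c(HC = 4L, MCI = 4L, AD = 4L),
      biomarkers = c(tinyA = 4L, tinyB = 4L), seed = seed
    ),
    paper_like = sim_config(seed = seed),
    planted = sim_config(
      n_per_group = c(HC = 100L, MCI = 100L, AD = 100L),
      biomarkers = c(panelA = 30L, panelB = 20L),
      effects = planted_effects(), seed = seed
    )
  )
  simulate_cohort(cfg)
}

#' Effect set of the planted fixture
#'
#' Regions 1-3 of panelA each drive all three cognitive scores in AD
#' subjects only (MMSE with negative sign - higher MMSE is better - CDRSB
#' and ADAS positive).
#'
#' @return List of [effect_spec()] objects.
#' @export
planted_effects <- function() {
  out <- list()
  for (r in 1:3)
    for (tg in .targets)
      out[[length(out) + 1L]] <- effect_spec(
        "panelA", r, tg,
        slope = if (tg == "MMSE") -.planted_slope else .planted_slope,
        active = "AD"
      )
  out
}
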