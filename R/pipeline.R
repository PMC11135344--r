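# End-to-end orchestration: for every (group x biomarker x target) cell,
# run the resampling loop and permutation null, build the NI profile; per
# (group x biomarker), build the cross-score consensus map; record a
# manifest sufficient to reproduce any cell in isolation.

#' Run the full biomarker-ranking pipeline on a cohort
#'
#' For each requested group, biomarker and target: repeated train/test
#' evaluation ([ert_resample()]), label-shuffled permutation null
#' ([ert_perm_null()]), and the NI profile with significance flags
#' ([ni_profile()]).  For each (group, biomarker): the cross-score
#' [consensus()] map over the targets run.  A failed cell is recorded in
#' the manifest with its error; remaining cells proceed.
#'
#' The `ci` profile runs 100 iterations and 100 permutations per cell; the
#' `paper` profile 500 of each.  Both use 50-tree ensembles and 90/10
#' splits.  Explicit `iterations` / `permutations` arguments override the
#' profile.
#'
#' @param cohort An `ert_cohort`.
#' @param groups Character vector of group names (default all four).
#' @param biomarkers Biomarker names (default: all in the cohort).
#' @param targets Cognitive scores (default MMSE, CDRSB, ADAS).
#' @param profile `"ci"` or `"paper"`.
#' @param iterations,permutations Optional overrides of the profile.
#' @param n_trees,train_frac,mtry_fraction,min_leaf,max_surrogates
#'   Ensemble and resampling parameters.
#' @param seed Integer master seed; each cell's seeds are derived from it
#'   and recorded in the manifest.
#' @param out_dir Optional output directory; when given, writes
#'   `<group>/<biomarker>/<target>/{iterations.json,null.json,ni.json}`,
#'   `<group>/<biomarker>/consensus.csv` and `manifest.json`.
#' @return Object of class `ert_pipeline`: `cells` (named list with
#'   `resample`, `null`, `profile` per completed cell), `consensus`
#'   (named list per group/biomarker) and `manifest`.
#' @export
run_pipeline <- function(cohort,
                         groups = c("HC_MCI", "HC_AD", "MCI_AD",
                                    "HC_MCI_AD"),
                         biomarkers = names(cohort$matrices),
                         targets = c("MMSE", "CDRSB", "ADAS"),
                         profile = c("ci", "paper"),
                         iterations = NULL, permutations = NULL,
                         n_trees = 50L, train_frac = 0.9,
                         mtry_fraction = 1 / 3, min_leaf = 5L,
                         max_surrogates = 10L, seed = 1L,
                         out_dir = NULL) {
  profile <- match.arg(profile)
  if (is.null(iterations))
    iterations <- if (profile == "paper") 500L else 100L
  if (is.null(permutations))
    permutations <- if (profile == "paper") 500L else 100L

  cells <- list()
  consensus_maps <- list()
  manifest_cells <- list()
  cell_i <- 0L
  for (g in groups) {
    for (bm in biomarkers) {
      profs <- list()
      for (tg in targets) {
        cell_i <- cell_i + 1L
        id <- paste(g, bm, tg, sep = "/")
        cell_seed <- .derive_seed(seed, cell_i, 11L)
        rec <- list(id = id, group = g, biomarker = bm, target = tg,
                    seed = cell_seed, iterations = iterations,
                    permutations = permutations, status = "ok")
        res <- tryCatch({
          sel <- select_group(cohort, g, bm, tg)
          rs <- ert_resample(sel$X, sel$y, n_iter = iterations,
                             train_frac = train_frac, n_trees = n_trees,
                             mtry_fraction = mtry_fraction,
                             min_leaf = min_leaf,
                             max_surrogates = max_surrogates,
                             seed = cell_seed)
          nl <- ert_perm_null(sel$X, sel$y, n_perm = permutations,
                              train_frac = train_frac,
                              n_trees = n_trees,
                              mtry_fraction = mtry_fraction,
                              min_leaf = min_leaf,
                              max_surrogates = max_surrogates,
                              seed = .derive_seed(cell_seed, 1L, 13L))
          pr <- ni_profile(rs, nl, biomarker = bm, group = g,
                           target = tg)
          list(resample = rs, null = nl, profile = pr)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rec$status <- "error"
          rec$error <- conditionMessage(res)
        } else {
          cells[[id]] <- res
          profs[[tg]] <- res$profile
          if (!is.null(out_dir)) {
            d <- file.path(out_dir, g, bm, tg)
            dir.create(d, showWarnings = FALSE, recursive = TRUE)
            .write_json(list(mse = res$resample$mse,
                             corr = res$resample$corr,
                             importance_mean =
                               colMeans(res$resample$importance),
                             seeds = res$resample$seeds),
                        file.path(d, "iterations.json"))
            .write_json(list(ni = res$null$ni, seeds = res$null$seeds),
                        file.path(d, "null.json"))
            .write_json(unclass(res$profile), file.path(d, "ni.json"))
          }
        }
        manifest_cells[[id]] <- rec
      }
      if (length(profs) == 3) {
        cm <- consensus(unname(profs))
        consensus_maps[[paste(g, bm, sep = "/")]] <- cm
        if (!is.null(out_dir))
          write_consensus(cm, file.path(out_dir, g, bm,
                                        "consensus.csv"))
      }
    }
  }
  manifest <- list(
    package = "ertni",
    version = as.character(utils::packageVersion("ertni")),
    profile = profile, seed = as.integer(seed),
    config = list(n_trees = n_trees, train_frac = train_frac,
                  mtry_fraction = mtry_fraction, min_leaf = min_leaf,
                  max_surrogates = max_surrogates,
                  iterations = iterations, permutations = permutations),
    cells = unname(manifest_cells)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_json(manifest, file.path(out_dir, "manifest.json"))
  }
  structure(list(cells = cells, consensus = consensus_maps,
                 manifest = manifest),
            class = "ert_pipeline")
}

#' @export
print.ert_pipeline <- function(x, ...) {
  st <- vapply(x$manifest$cells, function(c) c$status, character(1))
  cat("ert_pipeline:", length(st), "cells (", sum(st == "ok"), "ok,",
      sum(st != "ok"), "failed ),", length(x$consensus),
      "consensus maps\n")
  invisible(x)
}
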