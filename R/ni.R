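# Normalized importance (NI), permutation threshold, region ranking,
# cross-group standardization and cross-score consensus.

#' Normalized importance from an iteration importance matrix
#'
#' Averages the per-iteration importance vectors, takes the square root,
#' and rescales so the mean over regions is exactly one: with column means
#' `m`, `ni = sqrt(m) / mean(sqrt(m))`.  The mean-one property makes NI
#' profiles comparable across biomarkers with different region counts and
#' importance scales, and is invariant to multiplying the whole importance
#' matrix by a positive constant.
#'
#' @param importance `n_iter x n_regions` matrix of nonnegative importance
#'   values (or a single importance vector, or an [ert_resample()] result).
#' @return Numeric NI vector with `mean(ni) == 1`.
#' @export
compute_ni <- function(importance) {
  if (inherits(importance, "ert_resample"))
    importance <- importance$importance
  if (is.null(dim(importance)))
    importance <- matrix(importance, nrow = 1)
  if (anyNA(importance) || any(importance < 0))
    stop("importance must be nonnegative with no missing values")
  m <- colMeans(importance)
  if (all(m == 0)) stop("no splits recorded; NI undefined")
  s <- sqrt(m)
  stats::setNames(s / mean(s), colnames(importance))
}

#' Permutation-null significance threshold
#'
#' Pools every entry of the permuted NI matrix and returns
#' `mean + 2 * SD` (sample SD, n-1 denominator) - the parenthetically
#' defined "95th percentile" of the permutation distribution.  With
#' `type = "per_region"` the same statistic is computed per column
#' instead.
#'
#' @param perm_ni `n_perm x n_regions` matrix of permuted NI values, or an
#'   [ert_perm_null()] result.  `NA` rows (no-split runs) are dropped.
#' @param type `"pooled"` (one scalar, default) or `"per_region"`.
#' @return Threshold scalar (or vector for `"per_region"`).
#' @export
ni_threshold <- function(perm_ni, type = c("pooled", "per_region")) {
  type <- match.arg(type)
  if (inherits(perm_ni, "ert_permnull")) perm_ni <- perm_ni$ni
  if (is.null(dim(perm_ni))) perm_ni <- matrix(perm_ni, nrow = 1)
  keep <- !apply(perm_ni, 1L, anyNA)
  perm_ni <- perm_ni[keep, , drop = FALSE]
  if (!nrow(perm_ni)) stop("no usable permutation rows")
  if (type == "pooled") {
    v <- as.numeric(perm_ni)
    s <- stats::sd(v)
    if (length(v) < 2 || s == 0) {
      message("degenerate permutation distribution; threshold = mean")
      return(mean(v))
    }
    mean(v) + 2 * s
  } else {
    m <- colMeans(perm_ni)
    s <- apply(perm_ni, 2L, stats::sd)
    if (any(s == 0))
      message("degenerate permutation distribution in some regions")
    m + 2 * s
  }
}

#' Flag and rank regions against a threshold
#'
#' @param ni NI vector.
#' @param threshold Scalar (or per-region vector) threshold.
#' @return List with `significant` (strict `ni > threshold`) and
#'   `rank_order` (region indices by descending NI, ties broken by lower
#'   index).
#' @export
flag_and_rank <- function(ni, threshold) {
  if (length(threshold) != 1 && length(threshold) != length(ni))
    stop("threshold length must be 1 or match ni")
  list(significant = as.vector(ni > threshold),
       rank_order = order(-ni, seq_along(ni)))
}

#' Normalized-importance profile for one analysis cell
#'
#' Combines an iteration result and its permutation null into the
#' per-region NI profile: NI values, permutation threshold, significance
#' flags and rank order.
#'
#' @param resample An [ert_resample()] result (or importance matrix).
#' @param null An [ert_perm_null()] result (or permuted-NI matrix).
#' @param biomarker,group,target Optional labels carried in the profile.
#' @param threshold_type Passed to [ni_threshold()].
#' @return Object of class `ni_profile`.
#' @export
ni_profile <- function(resample, null, biomarker = NULL, group = NULL,
                       target = NULL, threshold_type = "pooled") {
  ni <- compute_ni(resample)
  thr <- ni_threshold(null, type = threshold_type)
  fr <- flag_and_rank(ni, thr)
  structure(
    list(ni = ni, threshold = thr, significant = fr$significant,
         rank_order = fr$rank_order,
         region_names = names(ni),
         biomarker = biomarker, group = group, target = target),
    class = "ni_profile"
  )
}

#' @export
print.ni_profile <- function(x, ...) {
  lab <- paste(Filter(Negate(is.null),
                      list(x$biomarker, x$group, x$target)),
               collapse = " / ")
  cat("ni_profile", if (nzchar(lab)) paste0("(", lab, ")"), "\n")
  cat(sprintf("  %d regions, threshold %.3f, %d significant\n",
              length(x$ni), x$threshold[1], sum(x$significant)))
  k <- x$rank_order[seq_len(min(5, length(x$ni)))]
  nm <- if (is.null(x$region_names)) k else x$region_names[k]
  cat("  top regions:",
      paste(sprintf("%s (%.2f)", nm, x$ni[k]), collapse = ", "), "\n")
  invisible(x)
}

#' Standardize NI profiles across the four diagnostic groups
#'
#' Joint min-max rescaling of the pooled `4 x n_regions` NI values to
#' [0, 1] for color mapping (lowest pooled NI maps to 0, highest to 1);
#' rendering is a separate concern.
#'
#' @param profiles List of four `ni_profile`s (same biomarker/target, same
#'   region order), or a numeric matrix with groups in rows.
#' @return `4 x n_regions` numeric matrix of display values.
#' @export
standardize_across_groups <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    regions <- lapply(profiles, function(p) p$region_names)
    for (r in regions[-1])
      if (!identical(r, regions[[1]]))
        stop("profiles have mismatched region order")
    m <- do.call(rbind, lapply(profiles, function(p) as.numeric(p$ni)))
    rownames(m) <- vapply(profiles, function(p) {
      if (is.null(p$group)) "" else as.character(p$group)
    }, character(1))
    colnames(m) <- regions[[1]]
  } else {
    m <- as.matrix(profiles)
  }
  rng <- range(m)
  if (diff(rng) == 0) {
    warning("all NI values identical; display values set to 0")
    m[] <- 0
    return(m)
  }
  (m - rng[1]) / diff(rng)
}

#' Cross-score consensus map
#'
#' Counts, per region, for how many of the three cognitive scores (MMSE,
#' CDRSB, ADAS) the region is flagged significant - the four overlap
#' states 0 to 3.
#'
#' @param profiles List of three `ni_profile`s for the same biomarker,
#'   group and region order, one per target.
#' @return Object of class `consensus_map`: data.frame with columns
#'   `region`, `consensus`, and one NI column per target.
#' @export
consensus <- function(profiles) {
  if (length(profiles) != 3) stop("need one profile per cognitive score")
  regions <- lapply(profiles, function(p) p$region_names)
  for (r in regions[-1])
    if (!identical(r, regions[[1]]))
      stop("profiles have mismatched region order")
  bms <- unique(unlist(lapply(profiles, function(p) p$biomarker)))
  grs <- unique(unlist(lapply(profiles, function(p) p$group)))
  if (length(bms) > 1 || length(grs) > 1)
    stop("profiles mix biomarkers or groups")
  sig <- vapply(profiles, function(p) as.logical(p$significant),
                logical(length(profiles[[1]]$ni)))
  cnt <- as.integer(rowSums(as.matrix(sig)))
  nm <- regions[[1]]
  if (is.null(nm)) nm <- paste0("R", seq_along(cnt))
  out <- data.frame(region = nm, consensus = cnt,
                    stringsAsFactors = FALSE)
  for (p in profiles) {
    tg <- if (is.null(p$target)) paste0("t", ncol(out)) else p$target
    out[[paste0("ni_", tolower(tg))]] <- as.numeric(p$ni)
  }
  structure(out, class = c("consensus_map", "data.frame"),
            biomarker = if (length(bms)) bms else NULL,
            group = if (length(grs)) grs else NULL)
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("consensus_map:", nrow(x), "regions; states",
      paste(sprintf("%d:%d", 0:3, tabulate(x$consensus + 1L, 4L)),
            collapse = " "), "\n")
  top <- x[order(-x$consensus), , drop = FALSE]
  print.data.frame(utils::head(top, 8))
  invisible(x)
}

#' Write a consensus map to CSV
#'
#' Columns: `region,consensus,ni_mmse,ni_cdrsb,ni_adas`.
#'
#' @param map A [consensus()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_consensus <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
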