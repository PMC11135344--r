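#' @useDynLib ertni, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov chisq.test cor oneway.test pf rnorm runif sd
#'   TukeyHSD var
#' @importFrom utils read.csv write.csv
NULL

# Canonical region counts per named biomarker.  Other biomarker names are
# allowed (fixtures, custom panels) and carry no count constraint.
.canonical_regions <- c(
  VGM = 68L, ATH = 68L, SA = 70L, VWM = 45L,
  FA = 57L, MD = 57L, RD = 57L, LD = 57L, ABETA = 109L
)

.diagnoses <- c("HC", "MCI", "AD")
.sexes <- c("M", "F")
.targets <- c("MMSE", "CDRSB", "ADAS")
.score_ranges <- list(MMSE = c(0, 30), CDRSB = c(0, 18), ADAS = c(0, 70))
.score_cols <- c(MMSE = "mmse", CDRSB = "cdrsb", ADAS = "adas")

#' Canonical biomarkers and their region counts
#'
#' The nine region-level biomarkers handled with fixed parcellation sizes:
#' gray-matter volume (VGM, 68 cortical regions), average cortical thickness
#' (ATH, 68), surface area (SA, 70), white-matter volume (VWM, 45), the four
#' DTI diffusivity measures (FA/MD/RD/LD, 57 each), and amyloid-beta PET
#' deposition (ABETA, 109).  Matrices under any other biomarker name are
#' accepted with arbitrary region counts.
#'
#' @return Named integer vector of region counts.
#' @export
canonical_biomarkers <- function() .canonical_regions

#' Desikan-Killiany cortical region names
#'
#' The 68 left/right cortical region labels of the Desikan-Killiany
#' parcellation, used as default region names for the 68-region biomarkers
#' (VGM, ATH).  Names are informative only; validation enforces counts, not
#' identities.
#'
#' @return Character vector of length 68.
#' @export
dk_regions <- function() {
  path <- system.file("extdata", "desikan_killiany_regions.txt",
                      package = "ertni")
  readLines(path)
}

#' Construct a validated subject metadata table
#'
#' @param df data.frame with columns subject_id, diagnosis (HC/MCI/AD),
#'   sex (M/F), age (> 0 years), mmse (0-30), cdrsb (0-18), adas (0-70).
#' @return The validated data.frame with diagnosis and sex as factors.
#' @export
subject_table <- function(df) {
  need <- c("subject_id", "diagnosis", "sex", "age", "mmse", "cdrsb", "adas")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in metadata")
  bad <- !df$diagnosis %in% .diagnoses
  if (any(bad))
    stop("invalid diagnosis for subject ", df$subject_id[which(bad)[1]],
         " (must be HC, MCI or AD)")
  bad <- !df$sex %in% .sexes
  if (any(bad))
    stop("invalid sex for subject ", df$subject_id[which(bad)[1]])
  check_range <- function(x, lo, hi, what) {
    bad <- !is.finite(x) | x < lo | x > hi
    if (any(bad))
      stop(what, " out of range [", lo, ", ", hi, "] for subject ",
           df$subject_id[which(bad)[1]])
  }
  if (any(!is.finite(df$age) | df$age <= 0))
    stop("age must be a positive number for subject ",
         df$subject_id[which(!is.finite(df$age) | df$age <= 0)[1]])
  check_range(df$mmse, 0, 30, "mmse")
  check_range(df$cdrsb, 0, 18, "cdrsb")
  check_range(df$adas, 0, 70, "adas")
  df$diagnosis <- factor(df$diagnosis, levels = .diagnoses)
  df$sex <- factor(df$sex, levels = .sexes)
  rownames(df) <- NULL
  df
}

#' Construct a validated biomarker matrix
#'
#' @param biomarker Biomarker name.  The nine canonical names (see
#'   [canonical_biomarkers()]) must carry their canonical region count.
#' @param values Numeric matrix, subjects in rows, regions in columns; no
#'   missing values.
#' @param subject_ids Character vector aligned to rows.
#' @param region_names Optional unique column names (default: column names of
#'   `values`, else `R1..Rp`).
#' @return An object of class `biomarker_matrix`.
#' @export
biomarker_matrix <- function(biomarker, values, subject_ids,
                             region_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(region_names)) region_names <- colnames(values)
  if (is.null(region_names))
    region_names <- paste0("R", seq_len(ncol(values)))
  if (length(region_names) != ncol(values))
    stop("region_names length does not match matrix columns")
  if (anyDuplicated(region_names))
    stop("region names must be unique (", biomarker, ")")
  if (biomarker %in% names(.canonical_regions) &&
      ncol(values) != .canonical_regions[[biomarker]])
    stop(sprintf("%s expects %d regions, got %d", biomarker,
                 .canonical_regions[[biomarker]], ncol(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length does not match matrix rows (", biomarker, ")")
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite values in ", biomarker, " matrix")
  dimnames(values) <- list(NULL, region_names)
  structure(
    list(biomarker = biomarker, values = values,
         subject_ids = as.character(subject_ids),
         region_names = region_names),
    class = "biomarker_matrix"
  )
}

#' Assemble a cohort from metadata and biomarker matrices
#'
#' A cohort pairs a subject metadata table with one feature matrix per
#' biomarker.  Biomarkers may cover different subject subsets (modalities are
#' acquired independently), but every matrix row must refer to a subject
#' present in the metadata.
#'
#' @param subjects Validated metadata (see [subject_table()]).
#' @param matrices Named list of [biomarker_matrix()] objects.
#' @return An object of class `ert_cohort`.
#' @export
cohort <- function(subjects, matrices) {
  subjects <- subject_table(subjects)
  if (is.null(names(matrices)) || any(names(matrices) == ""))
    stop("matrices must be a named list")
  for (bm in names(matrices)) {
    m <- matrices[[bm]]
    if (!inherits(m, "biomarker_matrix"))
      stop("matrices[['", bm, "']] is not a biomarker_matrix")
    unknown <- setdiff(m$subject_ids, subjects$subject_id)
    if (length(unknown))
      stop("matrix ", bm, " refers to unknown subject ", unknown[1])
  }
  structure(list(subjects = subjects, matrices = matrices),
            class = "ert_cohort")
}

#' @export
print.ert_cohort <- function(x, ...) {
  tab <- table(x$subjects$diagnosis)
  cat("ert_cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  for (bm in names(x$matrices)) {
    m <- x$matrices[[bm]]
    cat(sprintf("  %-6s %4d subjects x %3d regions\n", bm,
                nrow(m$values), ncol(m$values)))
  }
  invisible(x)
}

#' Analysis group specification
#'
#' The four diagnostic groupings analysed throughout: HC/MCI, HC/AD, MCI/AD
#' and HC/MCI/AD.
#'
#' @param name One of `"HC_MCI"`, `"HC_AD"`, `"MCI_AD"`, `"HC_MCI_AD"`.
#' @return List with `name` and `members` (the diagnoses pooled).
#' @export
group_spec <- function(name = c("HC_MCI", "HC_AD", "MCI_AD", "HC_MCI_AD")) {
  name <- match.arg(name)
  members <- strsplit(name, "_", fixed = TRUE)[[1]]
  structure(list(name = name, members = members), class = "group_spec")
}

#' Extract a (features, score) prediction task from a cohort
#'
#' Restricts to subjects whose diagnosis falls in the group and who have a
#' row in the requested biomarker's matrix; returns the feature matrix with
#' the chosen cognitive score aligned to its rows.
#'
#' @param cohort An [cohort()] object.
#' @param group A [group_spec()] or group name string.
#' @param biomarker Biomarker name present in the cohort.
#' @param target `"MMSE"`, `"CDRSB"` or `"ADAS"`.
#' @return List with `X` (matrix), `y` (numeric), `ids` (character).
#' @export
select_group <- function(cohort, group, biomarker,
                         target = c("MMSE", "CDRSB", "ADAS")) {
  target <- match.arg(target)
  if (is.character(group)) group <- group_spec(group)
  m <- cohort$matrices[[biomarker]]
  if (is.null(m)) stop("biomarker ", biomarker, " not present in cohort")
  sub <- cohort$subjects
  keep_ids <- sub$subject_id[sub$diagnosis %in% group$members]
  rows <- which(m$subject_ids %in% keep_ids)
  if (!length(rows))
    stop("no subjects in group ", group$name, " for biomarker ", biomarker)
  ids <- m$subject_ids[rows]
  y <- sub[[.score_cols[[target]]]][match(ids, sub$subject_id)]
  list(X = m$values[rows, , drop = FALSE], y = y, ids = ids)
}

#' Read a cohort from CSV files
#'
#' The metadata CSV has columns
#' `subject_id,diagnosis,sex,age,mmse,cdrsb,adas`; each matrix CSV has a
#' `subject_id` column followed by one column per region.  Matrix rows with
#' any missing value are dropped from that matrix only (with a message);
#' out-of-range scores or wrong canonical region counts are errors.
#'
#' @param metadata_path Path to the metadata CSV.
#' @param matrix_paths Named character vector/list, biomarker -> CSV path.
#' @return An `ert_cohort`.
#' @export
read_cohort <- function(metadata_path, matrix_paths) {
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  subjects <- subject_table(meta)
  mats <- list()
  for (bm in names(matrix_paths)) {
    path <- matrix_paths[[bm]]
    if (!file.exists(path)) stop("matrix file not found: ", path)
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(df))
      stop("matrix ", path, " lacks a subject_id column")
    ids <- as.character(df$subject_id)
    vals <- as.matrix(df[setdiff(names(df), "subject_id")])
    storage.mode(vals) <- "double"
    drop <- apply(vals, 1L, anyNA)
    if (any(drop)) {
      message(sum(drop), " row(s) with missing values dropped from ", bm)
      vals <- vals[!drop, , drop = FALSE]
      ids <- ids[!drop]
    }
    mats[[bm]] <- biomarker_matrix(bm, vals, ids)
  }
  cohort(subjects, mats)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: numeric values are written with 17 significant
#' digits so a read/write round trip reproduces finite doubles bit-exactly.
#'
#' @param cohort An `ert_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf("%.17g", x)
  meta <- cohort$subjects
  out <- data.frame(
    subject_id = meta$subject_id,
    diagnosis = as.character(meta$diagnosis),
    sex = as.character(meta$sex),
    age = fmt(meta$age), mmse = fmt(meta$mmse),
    cdrsb = fmt(meta$cdrsb), adas = fmt(meta$adas),
    stringsAsFactors = FALSE
  )
  files <- c(metadata = file.path(dir, "metadata.csv"))
  write.csv(out, files[["metadata"]], row.names = FALSE, quote = FALSE)
  for (bm in names(cohort$matrices)) {
    m <- cohort$matrices[[bm]]
    df <- data.frame(subject_id = m$subject_ids, stringsAsFactors = FALSE)
    for (j in seq_along(m$region_names))
      df[[m$region_names[j]]] <- fmt(m$values[, j])
    f <- file.path(dir, paste0(bm, ".csv"))
    write.csv(df, f, row.names = FALSE, quote = FALSE)
    files[[bm]] <- f
  }
  invisible(files)
}
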