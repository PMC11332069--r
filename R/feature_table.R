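#' Construct a feature table
#'
#' The central container of the workflow: an LC-MS feature-by-sample
#' intensity matrix with per-feature m/z and retention time and per-sample
#' role metadata (study group, QC flag, DATAN derivatization chirality of QC
#' pools). Missing intensities are `NA`; zeros read from file are treated as
#' missing (an unmeasured peak, not a true zero).
#'
#' @param features data.frame with columns `feature_id` (unique character),
#'   `mz` (Th, finite and > 0) and `rt` (minutes, >= 0).
#' @param intensity numeric matrix, rows matching `features$feature_id`,
#'   columns matching `samples$sample`; non-negative or `NA`.
#' @param samples data.frame with columns `sample` (unique character),
#'   `group` (`"positive"`, `"negative"`, or `NA` for QC samples),
#'   `is_qc` (logical) and `datan_chirality`
#'   (`"plus"`/`"minus"` for QC samples, `"none"` otherwise).
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(features, intensity, samples) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  rownames(intensity) <- as.character(features$feature_id)
  colnames(intensity) <- as.character(samples$sample)
  ft <- structure(
    list(features = features, intensity = intensity, samples = samples),
    class = "FeatureTable"
  )
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "FeatureTable"))
  f <- ft$features; s <- ft$samples; m <- ft$intensity
  need_f <- c("feature_id", "mz", "rt")
  if (!all(need_f %in% names(f)))
    stop("feature table: missing feature columns: ",
         paste(setdiff(need_f, names(f)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(f$feature_id)) {
    dup <- f$feature_id[duplicated(f$feature_id)][1L]
    stop("feature table: duplicate feature_id '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(s$sample)) {
    dup <- s$sample[duplicated(s$sample)][1L]
    stop("feature table: duplicate sample name '", dup, "'", call. = FALSE)
  }
  bad <- which(!is.finite(f$mz) | f$mz <= 0)
  if (length(bad))
    stop("feature table: non-positive or non-finite mz for feature '",
         f$feature_id[bad[1L]], "'", call. = FALSE)
  bad <- which(!is.finite(f$rt) | f$rt < 0)
  if (length(bad))
    stop("feature table: negative or non-finite rt for feature '",
         f$feature_id[bad[1L]], "'", call. = FALSE)
  if (nrow(m) != nrow(f) || ncol(m) != nrow(s))
    stop("feature table: intensity matrix shape does not match metadata",
         call. = FALSE)
  if (any(m < 0, na.rm = TRUE))
    stop("feature table: negative intensities present", call. = FALSE)
  need_s <- c("sample", "group", "is_qc", "datan_chirality")
  if (!all(need_s %in% names(s)))
    stop("feature table: missing sample columns: ",
         paste(setdiff(need_s, names(s)), collapse = ", "), call. = FALSE)
  bad <- which(!s$is_qc & !(s$group %in% c("positive", "negative")))
  if (length(bad))
    stop("feature table: non-QC sample '", s$sample[bad[1L]],
         "' lacks a valid group", call. = FALSE)
  bad <- which(s$is_qc & !(s$datan_chirality %in% c("plus", "minus")))
  if (length(bad))
    stop("feature table: QC sample '", s$sample[bad[1L]],
         "' lacks a DATAN chirality", call. = FALSE)
  invisible(ft)
}

#' @export
print.FeatureTable <- function(x, ...) {
  ns <- x$samples
  cat(sprintf("FeatureTable: %d features x %d samples (%d positive, %d negative, %d QC)\n",
              nrow(x$features), nrow(ns),
              sum(!ns$is_qc & ns$group == "positive"),
              sum(!ns$is_qc & ns$group == "negative"),
              sum(ns$is_qc)))
  cat(sprintf("  m/z %.4f-%.4f Th, RT %.2f-%.2f min, %.1f%% missing\n",
              min(x$features$mz), max(x$features$mz),
              min(x$features$rt), max(x$features$rt),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$intensity)

# Column indices of study (non-QC) samples, optionally one group.
study_samples <- function(ft, group = NULL) {
  keep <- !ft$samples$is_qc
  if (!is.null(group)) {
    if (!group %in% c("positive", "negative"))
      stop("unknown group label '", group, "'", call. = FALSE)
    keep <- keep & ft$samples$group == group
  }
  which(keep)
}

# Column indices of QC samples of one DATAN chirality.
qc_samples <- function(ft, chirality) {
  which(ft$samples$is_qc & ft$samples$datan_chirality == chirality)
}
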