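#' Mass difference in parts per million
#'
#' `|mz_a - mz_b| / mean(mz_a, mz_b) * 1e6`. The denominator is the mean of
#' the two masses; at the 5 ppm scale used for pairing the choice of
#' denominator is immaterial.
#'
#' @param mz_a,mz_b masses (Th), > 0. Vectorized.
#' @return ppm difference(s).
#' @export
ppm_difference <- function(mz_a, mz_b) {
  if (any(mz_a <= 0) || any(mz_b <= 0))
    stop("ppm_difference: masses must be > 0", call. = FALSE)
  abs(mz_a - mz_b) / ((mz_a + mz_b) / 2) * 1e6
}

#' Detect candidate enantiomer pairs
#'
#' After chiral derivatization an enantiomer pair appears as two features
#' with (nearly) identical mass and a small retention-time offset. All
#' unordered feature pairs with ppm difference strictly below `ppm_max` and
#' RT difference strictly between 0 and `rt_pair_max` are candidates.
#' Features claimed by more than one candidate are resolved greedily by
#' ascending ppm difference, then ascending RT difference, then
#' lexicographic feature ids, so that each feature joins at most one pair;
#' every greedy conflict resolution is reported via `message()`.
#'
#' @param ft a normalized [feature_table()].
#' @param config an [analysis_config()].
#' @return data.frame with columns `feature_a`, `feature_b`, `ppm_diff`,
#'   `rt_diff` (a < b lexicographically); zero rows if no candidates.
#' @export
detect_enantiomer_candidates <- function(ft, config = analysis_config()) {
  f <- ft$features
  n <- nrow(f)
  empty <- data.frame(feature_a = character(), feature_b = character(),
                      ppm_diff = numeric(), rt_diff = numeric(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ord <- order(f$mz)
  mz <- f$mz[ord]; rt <- f$rt[ord]; id <- f$feature_id[ord]
  cand <- vector("list", n)
  # sliding mass window keeps this near-linear for realistic tables
  lo <- 1L
  for (i in 2L:n) {
    while (ppm_difference(mz[lo], mz[i]) >= config$ppm_max && lo < i) lo <- lo + 1L
    if (lo >= i) next
    js <- lo:(i - 1L)
    ppm <- ppm_difference(mz[js], mz[i])
    drt <- abs(rt[js] - rt[i])
    keep <- ppm < config$ppm_max & drt > 0 & drt < config$rt_pair_max
    if (!any(keep)) next
    js <- js[keep]
    a <- pmin(id[js], id[i]); b <- pmax(id[js], id[i])
    cand[[i]] <- data.frame(feature_a = a, feature_b = b,
                            ppm_diff = ppm[keep], rt_diff = drt[keep],
                            stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- cand[order(cand$ppm_diff, cand$rt_diff, cand$feature_a,
                     cand$feature_b), , drop = FALSE]
  taken <- character(0)
  pick <- logical(nrow(cand))
  contested <- c(cand$feature_a, cand$feature_b)
  contested <- unique(contested[duplicated(contested)])
  for (k in seq_len(nrow(cand))) {
    if (cand$feature_a[k] %in% taken || cand$feature_b[k] %in% taken) next
    pick[k] <- TRUE
    taken <- c(taken, cand$feature_a[k], cand$feature_b[k])
  }
  if (length(contested))
    message("detect_enantiomer_candidates: greedy conflict resolution for ",
            length(contested), " feature(s) in multiple candidate pairs")
  out <- cand[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign abundance-ordered enantiomer labels
#'
#' Within a pair the lower mean intensity over study (non-QC) samples is
#' labeled E1 and the higher E2; an exact tie is broken by elution order
#' (earlier RT is E1).
#'
#' @param pairs data.frame from [detect_enantiomer_candidates()].
#' @param ft the [feature_table()] the pairs came from.
#' @return `pairs` with added columns `e1`, `e2`, `mean_e1`, `mean_e2`.
#' @export
assign_enantiomer_labels <- function(pairs, ft) {
  if (!nrow(pairs)) {
    pairs$e1 <- character(0); pairs$e2 <- character(0)
    pairs$mean_e1 <- numeric(0); pairs$mean_e2 <- numeric(0)
    return(pairs)
  }
  study <- study_samples(ft)
  means <- rowMeans(ft$intensity[, study, drop = FALSE], na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  names(means) <- ft$features$feature_id
  rt <- stats::setNames(ft$features$rt, ft$features$feature_id)
  e1 <- character(nrow(pairs)); e2 <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$feature_a[k]; b <- pairs$feature_b[k]
    ma <- means[[a]]; mb <- means[[b]]
    if (is.na(ma) && is.na(mb))
      stop("assign_enantiomer_labels: both members of pair (", a, ", ", b,
           ") are entirely missing", call. = FALSE)
    if (is.na(ma)) { e1[k] <- a; e2[k] <- b }       # all-missing = no abundance
    else if (is.na(mb)) { e1[k] <- b; e2[k] <- a }
    else if (ma < mb) { e1[k] <- a; e2[k] <- b }
    else if (mb < ma) { e1[k] <- b; e2[k] <- a }
    else if (rt[[a]] <= rt[[b]]) { e1[k] <- a; e2[k] <- b }
    else { e1[k] <- b; e2[k] <- a }
  }
  pairs$e1 <- e1; pairs$e2 <- e2
  pairs$mean_e1 <- unname(means[e1]); pairs$mean_e2 <- unname(means[e2])
  pairs
}

#' Verify a pair through DATAN elution-order switching
#'
#' A pooled QC derivatized with (+)-DATAN and a second aliquot derivatized
#' with (-)-DATAN swap the elution order of a true enantiomer pair: the peak
#' ratio at the two retention-time positions inverts between the pools.
#' With `R+` = intensity(E1)/intensity(E2) in the plus pool and `R-` the
#' same positional ratio in the minus pool, a pair is `verified` when
#' `log2(R+)` and `log2(R-)` have opposite signs and both magnitudes reach
#' `swap_tau`; `untestable` when either pool is absent or has a missing
#' value at either position; `not_verified` otherwise. With several QC
#' columns per chirality, intensities are averaged per pool first.
#'
#' @param pairs labeled pairs from [assign_enantiomer_labels()].
#' @param ft the [feature_table()].
#' @param config an [analysis_config()] (`swap_tau`).
#' @return `pairs` with added columns `swap_status`, `log2_ratio_plus`,
#'   `log2_ratio_minus`.
#' @export
verify_label_swap <- function(pairs, ft, config = analysis_config()) {
  plus <- qc_samples(ft, "plus"); minus <- qc_samples(ft, "minus")
  qc_val <- function(cols, fid) {
    if (!length(cols)) return(NA_real_)
    v <- ft$intensity[fid, cols]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  status <- character(nrow(pairs))
  l2p <- rep(NA_real_, nrow(pairs)); l2m <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p1 <- qc_val(plus, pairs$e1[k]);  p2 <- qc_val(plus, pairs$e2[k])
    m1 <- qc_val(minus, pairs$e1[k]); m2 <- qc_val(minus, pairs$e2[k])
    if (anyNA(c(p1, p2, m1, m2)) || any(c(p2, m2) == 0)) {
      status[k] <- "untestable"
      next
    }
    l2p[k] <- log2(p1 / p2); l2m[k] <- log2(m1 / m2)
    ok <- is.finite(l2p[k]) && is.finite(l2m[k]) &&
      l2p[k] * l2m[k] < 0 &&
      min(abs(l2p[k]), abs(l2m[k])) >= config$swap_tau
    status[k] <- if (ok) "verified" else "not_verified"
  }
  pairs$swap_status <- status
  pairs$log2_ratio_plus <- l2p
  pairs$log2_ratio_minus <- l2m
  pairs
}

#' Annotate features against a standards library
#'
#' Each feature is matched to the library entry minimizing the ppm error
#' among entries within `ppm_max` and `annotation_rt_tol`; ties on ppm error
#' break by smaller |RT error|. A feature receives at most one annotation;
#' unmatched features are reported as `unknown`.
#'
#' @param ft a normalized [feature_table()].
#' @param library a [read_standards()] data.frame.
#' @param config an [analysis_config()].
#' @return data.frame: `feature_id`, `compound`, `enantiomer`, `ppm_error`,
#'   `rt_error` (compound `"unknown"` and `NA` errors when unmatched).
#' @export
annotate_features <- function(ft, library, config = analysis_config()) {
  if (!nrow(library)) stop("annotate_features: empty standards library",
                           call. = FALSE)
  f <- ft$features
  out <- data.frame(feature_id = f$feature_id,
                    compound = "unknown", enantiomer = NA_character_,
                    ppm_error = NA_real_, rt_error = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(f))) {
    ppm <- ppm_difference(rep(f$mz[i], nrow(library)), library$expected_mz)
    rte <- f$rt[i] - library$expected_rt
    ok <- ppm <= config$ppm_max & abs(rte) <= config$annotation_rt_tol
    if (!any(ok)) next
    cand <- which(ok)
    best <- cand[order(ppm[cand], abs(rte[cand]))][1L]
    out$compound[i] <- library$compound[best]
    out$enantiomer[i] <- library$enantiomer[best]
    out$ppm_error[i] <- ppm[best]
    out$rt_error[i] <- rte[best]
  }
  out
}
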