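#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution by dividing each sample by the median of its
#' feature-wise quotients against a reference spectrum. The reference is the
#' per-feature median over the non-QC study samples; QC pools are normalized
#' with factors computed the same way against the same reference. Quotients
#' are formed only over features non-missing in both the sample and the
#' reference (no imputation).
#'
#' Because the median reference itself shifts when samples are rescaled, a
#' single median-quotient pass is not exactly idempotent; by default the
#' pass is repeated until every per-pass factor is 1 within `tol`
#' (geometric convergence, typically a few dozen cheap passes), which makes
#' the normalization a fixed point. The reported
#' `dilution_factor` is the per-sample product over passes;
#' `first_pass_factor` is the classical single-pass median quotient.
#' `max_iter = 1` gives the classical single-pass behaviour.
#'
#' @param ft a [feature_table()]; intensities on the raw scale.
#' @param max_iter maximum normalization passes (default 200).
#' @param tol convergence tolerance on per-pass factors (default 1e-12).
#' @return A list with `table` (the normalized `FeatureTable`) and `report`,
#'   a list holding the per-feature `reference` (first-pass median
#'   spectrum), per-sample `dilution_factor`, `first_pass_factor`,
#'   `n_features_used` and `iterations`.
#' @export
pqn_normalize <- function(ft, max_iter = 200L, tol = 1e-12) {
  validate_feature_table(ft)
  m <- ft$intensity
  study <- study_samples(ft)
  if (length(study) < 2L)
    stop("PQN requires >= 2 non-QC samples", call. = FALSE)
  total <- rep(1, ncol(m))
  first_pass <- NULL
  reference0 <- NULL
  n_used <- integer(ncol(m))
  cur <- m
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    reference <- apply(cur[, study, drop = FALSE], 1L, stats::median,
                       na.rm = TRUE)
    usable_ref <- is.finite(reference) & reference > 0
    factors <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
      ok <- usable_ref & !is.na(cur[, j])
      if (!any(ok))
        stop("PQN normalization error: sample '", ft$samples$sample[j],
             "' shares no features with the reference", call. = FALSE)
      factors[j] <- stats::median(cur[ok, j] / reference[ok])
      if (it == 1L) n_used[j] <- sum(ok)
    }
    if (it == 1L) { first_pass <- factors; reference0 <- reference }
    total <- total * factors
    cur <- sweep(cur, 2L, factors, `/`)
    iterations <- it
    if (max(abs(factors - 1)) < tol) break
  }
  out <- ft
  out$intensity <- cur
  report <- list(
    reference = stats::setNames(reference0, ft$features$feature_id),
    dilution_factor = stats::setNames(total, ft$samples$sample),
    first_pass_factor = stats::setNames(first_pass, ft$samples$sample),
    n_features_used = stats::setNames(n_used, ft$samples$sample),
    iterations = iterations)
  list(table = out, report = report)
}

#' Per-feature group mean abundance
#'
#' Arithmetic mean over the non-missing values of one study group; features
#' with no non-missing value get `NA`.
#'
#' @param ft a [feature_table()].
#' @param group `"positive"` or `"negative"`.
#' @return Named numeric vector (one value per feature).
#' @export
build_group_means <- function(ft, group) {
  cols <- study_samples(ft, group)
  v <- rowMeans(ft$intensity[, cols, drop = FALSE], na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  stats::setNames(v, ft$features$feature_id)
}
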