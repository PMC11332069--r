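#' One-tailed two-sample t-test
#'
#' Welch unequal-variance statistic by default (Student pooled-variance via
#' `var_equal`). With `tail_mode = "observed"` the p-value is the one-tailed
#' probability in the direction of the observed mean difference, i.e. the
#' two-tailed p divided by two — anti-conservative, and flagged as such in
#' pipeline output. Fixed modes (`"greater"`, `"less"`) test the stated
#' direction of `x` (group positive) versus `y` (group negative).
#'
#' @param x,y numeric vectors (positive / negative group); `NA`s dropped.
#' @param tail_mode see [analysis_config()].
#' @param var_equal pooled-variance Student test instead of Welch.
#' @param min_per_group minimum non-missing values per group; below it the
#'   result is flagged untested (`p = NA`).
#' @return list: `p_value`, `direction` (`up_in_positive`,
#'   `down_in_positive`, `none`), `statistic`, `df`, `n_pos`, `n_neg`,
#'   `tested`.
#' @export
one_tailed_ttest <- function(x, y, tail_mode = "observed",
                             var_equal = FALSE, min_per_group = 3L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < min_per_group || n2 < min_per_group)
    return(list(p_value = NA_real_, direction = "none",
                statistic = NA_real_, df = NA_real_,
                n_pos = n1, n_neg = n2, tested = FALSE))
  ws <- welch_stat(x, y, var_equal)
  diff <- mean(x) - mean(y)
  direction <- if (diff > 0) "up_in_positive"
               else if (diff < 0) "down_in_positive" else "none"
  p <- switch(tail_mode,
    observed = stats::pt(abs(ws$t), ws$df, lower.tail = FALSE),
    greater  = stats::pt(ws$t, ws$df, lower.tail = FALSE),
    less     = stats::pt(ws$t, ws$df, lower.tail = TRUE),
    stop("unknown tail_mode '", tail_mode, "'", call. = FALSE))
  list(p_value = p, direction = direction, statistic = ws$t, df = ws$df,
       n_pos = n1, n_neg = n2, tested = TRUE)
}

# intensities enter the t-test on the log2 scale by default (calibration
# under multiplicative noise); zeros are treated as missing upstream
test_scale <- function(v, config) {
  if (!isTRUE(config$test_on_log)) return(v)
  v[!is.na(v) & v <= 0] <- NA_real_
  log2(v)
}

# t statistic and df; Welch-Satterthwaite or pooled variance
welch_stat <- function(x, y, var_equal = FALSE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- if (se == 0) 0 else (mean(x) - mean(y)) / se
  list(t = t, df = df)
}

#' Two-tailed two-sample t-test
#'
#' Symmetric-tail companion of [one_tailed_ttest()] (used for clinical
#' characteristics).
#'
#' @inheritParams one_tailed_ttest
#' @return Two-sided p-value.
#' @export
two_tailed_ttest <- function(x, y, var_equal = FALSE, min_per_group = 2L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < min_per_group || length(y) < min_per_group)
    return(NA_real_)
  ws <- welch_stat(x, y, var_equal)
  2 * stats::pt(abs(ws$t), ws$df, lower.tail = FALSE)
}

#' Log2 fold change of group means
#'
#' `log2(mean(x) / mean(y))`, `NA` when either mean is non-positive or not
#' computable.
#'
#' @param x,y numeric vectors; `NA`s dropped.
#' @return log2 fold change.
#' @export
log2_fold_change <- function(x, y) {
  mx <- mean(x, na.rm = TRUE); my <- mean(y, na.rm = TRUE)
  if (!is.finite(mx) || !is.finite(my) || mx <= 0 || my <= 0)
    return(NA_real_)
  log2(mx / my)
}

#' Significance tier of a raw p-value
#'
#' `significant` for p < alpha; `borderline` for alpha <= p < borderline_hi
#' (reported with an asterisk in the original analysis); otherwise
#' `not_significant`. `NA` p-values (untested features) map to `untested`.
#'
#' @param p p-value(s) in (0, 1]; vectorized.
#' @param config an [analysis_config()].
#' @return Character vector of tiers.
#' @export
classify_tier <- function(p, config = analysis_config()) {
  out <- ifelse(is.na(p), "untested",
         ifelse(p < config$alpha, "significant",
         ifelse(p < config$borderline_hi, "borderline", "not_significant")))
  as.character(out)
}

#' Per-feature differential testing
#'
#' Runs [one_tailed_ttest()] and [log2_fold_change()] for every feature
#' (positive vs negative group) and assigns significance tiers. With the
#' default `test_on_log` the t-test sees log2 intensities while the fold
#' change uses raw-scale group means. P-values are raw; no multiple-testing
#' correction is applied, matching the original workflow.
#'
#' @param ft a normalized [feature_table()].
#' @param config an [analysis_config()].
#' @return data.frame (`DifferentialResult`): `feature_id`, `p_value`,
#'   `direction`, `log2_fc`, `tier`, `n_pos`, `n_neg`.
#' @export
differential_test <- function(ft, config = analysis_config()) {
  pos <- study_samples(ft, "positive"); neg <- study_samples(ft, "negative")
  res <- lapply(seq_len(nrow(ft$features)), function(i) {
    x <- ft$intensity[i, pos]; y <- ft$intensity[i, neg]
    tt <- one_tailed_ttest(test_scale(x, config), test_scale(y, config),
                           config$tail_mode, config$var_equal,
                           config$min_per_group)
    data.frame(feature_id = ft$features$feature_id[i],
               p_value = tt$p_value, direction = tt$direction,
               log2_fc = log2_fold_change(x, y),
               n_pos = tt$n_pos, n_neg = tt$n_neg,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$tier <- classify_tier(res$p_value, config)
  res[, c("feature_id", "p_value", "direction", "log2_fc", "tier",
          "n_pos", "n_neg")]
}

#' Gate pairs on single-form significance
#'
#' A pair passes the gate when at least one member's tier is `significant`
#' (borderline does not pass); only gated pairs are carried into downstream
#' interpretation.
#'
#' @param pairs labeled pairs data.frame.
#' @param results a [differential_test()] data.frame.
#' @return `pairs` with a logical `gate_passed` column.
#' @export
gate_pairs <- function(pairs, results) {
  tier <- stats::setNames(results$tier, results$feature_id)
  missing_ids <- setdiff(c(pairs$feature_a, pairs$feature_b), names(tier))
  if (length(missing_ids))
    stop("gate_pairs: no differential result for feature '", missing_ids[1L],
         "'", call. = FALSE)
  pairs$gate_passed <- tier[pairs$feature_a] == "significant" |
                       tier[pairs$feature_b] == "significant"
  pairs$gate_passed <- unname(pairs$gate_passed)
  pairs
}

#' Differential test of the pooled (E1 + E2) abundance
#'
#' Sums the two members' intensities per sample (total D+L pool) and runs
#' the same test and fold change on the summed vector. A sample missing one
#' member falls back to the other member alone; if a member is missing in
#' every sample the pool reduces to the other member and the result is
#' flagged (`pool_fallback`).
#'
#' @param pair one row of a labeled pairs data.frame.
#' @param ft the [feature_table()].
#' @param config an [analysis_config()].
#' @return One-row data.frame like [differential_test()] output with an
#'   extra `pool_fallback` flag; `feature_id` is `"<e1>+<e2>"`.
#' @export
pooled_test <- function(pair, ft, config = analysis_config()) {
  i1 <- match(pair$e1, ft$features$feature_id)
  i2 <- match(pair$e2, ft$features$feature_id)
  v1 <- ft$intensity[i1, ]; v2 <- ft$intensity[i2, ]
  pooled <- ifelse(is.na(v1) & is.na(v2), NA_real_,
                   ifelse(is.na(v1), v2, ifelse(is.na(v2), v1, v1 + v2)))
  fallback <- all(is.na(v1)) || all(is.na(v2))
  pos <- study_samples(ft, "positive"); neg <- study_samples(ft, "negative")
  x <- pooled[pos]; y <- pooled[neg]
  tt <- one_tailed_ttest(test_scale(x, config), test_scale(y, config),
                         config$tail_mode, config$var_equal,
                         config$min_per_group)
  data.frame(feature_id = paste0(pair$e1, "+", pair$e2),
             p_value = tt$p_value, direction = tt$direction,
             log2_fc = log2_fold_change(x, y),
             tier = classify_tier(tt$p_value, config),
             n_pos = tt$n_pos, n_neg = tt$n_neg,
             pool_fallback = fallback, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Exact-distribution two-sided p-value for combined n <= 20 without ties,
#' normal approximation with tie correction otherwise (used for clinical
#' characteristics such as age, weight and BMI). The reported `W` is the
#' Mann-Whitney U statistic of `x`.
#'
#' @param x,y numeric vectors, each non-empty; `NA`s dropped.
#' @return list: `W`, `p_two_sided`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("wilcoxon_rank_sum: both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)
  )
  list(W = unname(wt$statistic), p_two_sided = wt$p.value, exact = exact)
}
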