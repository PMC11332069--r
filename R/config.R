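#' Analysis configuration
#'
#' Collects every tunable threshold of the workflow in one validated object.
#' Defaults mirror the thresholds of the original analysis: a 5 ppm mass
#' window and a <3 min retention-time window for candidate enantiomer pairs,
#' raw (unadjusted) p < 0.05 significance with a 0.05--0.06 borderline band,
#' a 1.5 cutoff on |log2 fold change| for metabolite features and a linear
#' 1.5-fold cutoff for genes, a strict 0 < CV < 0.25 gene filter, Pearson
#' r >= 0.7 correlation edges, and a 0.2 pathway-impact reporting floor.
#'
#' @param ppm_max maximum m/z difference between pair members, in parts per
#'   million (strict `<`).
#' @param rt_pair_max maximum retention-time difference between pair members,
#'   minutes (strict `<`; pairs also need a strictly positive RT difference).
#' @param annotation_rt_tol retention-time tolerance for library annotation,
#'   minutes. A separate knob from `rt_pair_max`: the pairing window describes
#'   diastereomer separation, not identification accuracy.
#' @param alpha significance level on raw p-values.
#' @param borderline_hi upper bound of the borderline tier
#'   (`alpha <= p < borderline_hi`).
#' @param fc_log2_threshold reporting cutoff applied to metabolite |log2 FC|.
#' @param fc_log2_absolute apply `fc_log2_threshold` to |log2 FC| (default)
#'   rather than the signed value.
#' @param gene_fc_threshold linear fold-change cutoff for gene inclusion
#'   (strict `>`, with the reciprocal rule in absolute mode).
#' @param gene_fc_absolute also keep genes with FC below
#'   `1/gene_fc_threshold` (default) rather than up-only.
#' @param cv_lo,cv_hi strict bounds of the gene coefficient-of-variation
#'   filter.
#' @param r_min minimum Pearson correlation for a gene--metabolite edge
#'   (positive correlations only, `>=`).
#' @param impact_min minimum topology impact for the joint-pathway report
#'   (strict `>`).
#' @param swap_tau minimum |log2 ratio| in *both* QC pools for a pair to be
#'   called swap-verified. The original study reports "switching" without a
#'   numeric criterion, so this stays configurable.
#' @param tail_mode `"observed"` (one-tailed p in the direction of the
#'   observed difference, i.e. two-tailed/2), `"greater"` or `"less"`
#'   (fixed-direction tests of group positive vs negative).
#' @param var_equal use Student pooled-variance t statistics instead of the
#'   Welch default.
#' @param test_on_log run the per-feature t-tests on log2-transformed
#'   intensities (default). Intensities are log-normal to good
#'   approximation, so testing on the log scale keeps small-sample t-tests
#'   calibrated; fold changes are always computed from raw-scale group
#'   means.
#' @param min_per_group minimum non-missing values per group for a feature to
#'   be tested.
#' @param seed integer seed echoed into manifests; generators take their own
#'   seed argument.
#' @return A list of class `chiralome_config`.
#' @export
analysis_config <- function(ppm_max = 5,
                            rt_pair_max = 3,
                            annotation_rt_tol = 1.0,
                            alpha = 0.05,
                            borderline_hi = 0.06,
                            fc_log2_threshold = 1.5,
                            fc_log2_absolute = TRUE,
                            gene_fc_threshold = 1.5,
                            gene_fc_absolute = TRUE,
                            cv_lo = 0,
                            cv_hi = 0.25,
                            r_min = 0.7,
                            impact_min = 0.2,
                            swap_tau = 0.5,
                            tail_mode = c("observed", "greater", "less"),
                            var_equal = FALSE,
                            test_on_log = TRUE,
                            min_per_group = 3L,
                            seed = 1L) {
  tail_mode <- match.arg(tail_mode)
  cfg <- list(
    ppm_max = ppm_max, rt_pair_max = rt_pair_max,
    annotation_rt_tol = annotation_rt_tol,
    alpha = alpha, borderline_hi = borderline_hi,
    fc_log2_threshold = fc_log2_threshold,
    fc_log2_absolute = isTRUE(fc_log2_absolute),
    gene_fc_threshold = gene_fc_threshold,
    gene_fc_absolute = isTRUE(gene_fc_absolute),
    cv_lo = cv_lo, cv_hi = cv_hi,
    r_min = r_min, impact_min = impact_min,
    swap_tau = swap_tau, tail_mode = tail_mode,
    var_equal = isTRUE(var_equal),
    test_on_log = isTRUE(test_on_log),
    min_per_group = as.integer(min_per_group),
    seed = as.integer(seed)
  )
  class(cfg) <- "chiralome_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "chiralome_config"))
  with(cfg, {
    if (!(alpha > 0 && alpha < borderline_hi && borderline_hi < 1))
      stop("config invalid: need 0 < alpha < borderline_hi < 1", call. = FALSE)
    if (ppm_max <= 0) stop("config invalid: ppm_max must be > 0", call. = FALSE)
    if (rt_pair_max <= 0) stop("config invalid: rt_pair_max must be > 0", call. = FALSE)
    if (!(cv_lo < cv_hi)) stop("config invalid: need cv_lo < cv_hi", call. = FALSE)
    if (swap_tau < 0) stop("config invalid: swap_tau must be >= 0", call. = FALSE)
    if (min_per_group < 2) stop("config invalid: min_per_group must be >= 2", call. = FALSE)
  })
  invisible(cfg)
}

#' Read / write an analysis configuration as JSON
#'
#' @param path file path.
#' @return `read_config()` returns a `chiralome_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config a `chiralome_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.chiralome_config <- function(x, ...) {
  cat("chiralome analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
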