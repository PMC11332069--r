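#' Run the full analysis pipeline
#'
#' Executes the stages in order — read, PQN normalization, enantiomer-pair
#' detection, E1/E2 labeling, DATAN swap verification, library annotation,
#' per-feature differential testing, pair gating, CV gene filtering,
#' gene--metabolite correlation, pathway-gene overlap, joint pathway
#' analysis — and writes result CSVs plus a JSON run manifest. The run is a
#' pure function of (inputs, config): two identical runs produce identical
#' outputs.
#'
#' Stage selection: `stages` may restrict the run to a prefix-closed subset;
#' downstream stages that lack their prerequisites are skipped. The
#' metabolite abundance vectors for the correlation stage are the annotated
#' chiral features' normalized intensities over the positive-group samples
#' (missing values completed with the feature's row mean).
#'
#' @param features,samples,standards,expression,pathways,topology input file
#'   paths (see the `io` readers); `standards`, `expression`, `pathways`,
#'   `topology` are optional (`NULL` skips the dependent stages).
#' @param de_genes optional CSV (`gene`, `fc`: precomputed linear fold
#'   changes, e.g. from an external cohort DE analysis). When given, the
#'   joint-pathway gene query is [de_gene_filter()] applied to it; otherwise
#'   the correlated-edge genes are used.
#' @param out_dir output directory for results and manifest.
#' @param config an [analysis_config()].
#' @param stages character subset of
#'   `c("normalize", "pair", "test", "integrate")`.
#' @return Invisibly, a list with all stage outputs and the manifest path.
#' @export
run_pipeline <- function(features, samples, out_dir,
                         standards = NULL, expression = NULL,
                         pathways = NULL, topology = NULL, de_genes = NULL,
                         config = analysis_config(),
                         stages = c("normalize", "pair", "test", "integrate")) {
  validate_config(config)
  stage_on <- function(s) s %in% stages
  counts <- list()
  results <- list()
  out <- list()

  ft <- read_feature_table(features, samples)
  counts$features_in <- nrow(ft$features)
  counts$samples_in <- nrow(ft$samples)

  if (stage_on("normalize")) {
    norm <- pqn_normalize(ft)
    ft <- norm$table
    out$normalization <- norm$report
    results$dilution_factors <- data.frame(
      sample = names(norm$report$dilution_factor),
      dilution_factor = unname(norm$report$dilution_factor),
      n_features_used = unname(norm$report$n_features_used))
  }
  out$table <- ft

  pairs <- NULL
  if (stage_on("pair")) {
    pairs <- detect_enantiomer_candidates(ft, config)
    pairs <- assign_enantiomer_labels(pairs, ft)
    pairs <- verify_label_swap(pairs, ft, config)
    counts$pairs_found <- nrow(pairs)
    counts$pairs_swap_verified <- sum(pairs$swap_status == "verified")
  }

  annot <- NULL
  if (stage_on("pair") && !is.null(standards)) {
    lib <- read_standards(standards)
    annot <- annotate_features(ft, lib, config)
    counts$features_annotated <- sum(annot$compound != "unknown")
    results$annotations <- annot
  }

  diff_res <- NULL
  if (stage_on("test")) {
    diff_res <- differential_test(ft, config)
    counts$features_tested <- sum(diff_res$tier != "untested")
    counts$features_significant <- sum(diff_res$tier == "significant")
    counts$features_borderline <- sum(diff_res$tier == "borderline")
    counts$features_high_fc <- sum(
      !is.na(diff_res$log2_fc) &
        (if (config$fc_log2_absolute) abs(diff_res$log2_fc)
         else diff_res$log2_fc) > config$fc_log2_threshold)
    res_out <- diff_res
    if (!is.null(annot)) {
      res_out$annotation <- paste0(
        ifelse(is.na(annot$enantiomer) | annot$enantiomer == "achiral", "",
               paste0(annot$enantiomer, "-")),
        annot$compound)[match(res_out$feature_id, annot$feature_id)]
    }
    results$results <- res_out
    results$volcano <- data.frame(feature_id = diff_res$feature_id,
                                  log2_fc = diff_res$log2_fc,
                                  neg_log10_p = -log10(diff_res$p_value),
                                  tier = diff_res$tier)
    if (!is.null(pairs)) {
      pairs <- gate_pairs(pairs, diff_res)
      counts$pairs_gated <- sum(pairs$gate_passed)
      pooled <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
        pooled_test(pairs[k, ], ft, config)))
      if (!is.null(pooled)) results$pooled <- pooled
    }
  }
  if (!is.null(pairs)) {
    pcsv <- pairs
    if (!"gate_passed" %in% names(pcsv)) pcsv$gate_passed <- NA
    results$pairs <- pcsv[, c("feature_a", "feature_b", "ppm_diff", "rt_diff",
                              "e1", "e2", "swap_status", "gate_passed")]
    out$pairs <- pairs
  }
  out$annotations <- annot
  out$differential <- diff_res

  if (stage_on("integrate") && !is.null(expression) && !is.null(annot)) {
    expr <- read_expression(expression)
    kept <- cv_filter(expr, config)
    counts$genes_in <- nrow(expr)
    counts$genes_cv_passed <- length(kept)
    chiral <- annot[annot$compound != "unknown" &
                      !is.na(annot$enantiomer) &
                      annot$enantiomer != "achiral", , drop = FALSE]
    pos <- study_samples(out$table, "positive")
    met <- out$table$intensity[match(chiral$feature_id,
                                     out$table$features$feature_id),
                               pos, drop = FALSE]
    rownames(met) <- paste0(chiral$enantiomer, "-", chiral$compound)
    if (anyNA(met)) {
      rm_ <- rowMeans(met, na.rm = TRUE)
      for (r_ in seq_len(nrow(met))) met[r_, is.na(met[r_, ])] <- rm_[r_]
    }
    if (ncol(expr) != length(pos))
      stop("pipeline stage integrate: expression has ", ncol(expr),
           " samples but the positive group has ", length(pos), call. = FALSE)
    edges <- correlate(expr[kept, , drop = FALSE], met, config)
    counts$edges <- nrow(edges)
    results$edges <- edges
    out$edges <- edges

    if (!is.null(pathways)) {
      pw <- read_gmt(pathways, topology)
      results$overlap <- overlap_with_pathway_genes(edges, pw)
      gene_query <- unique(edges$gene)
      if (!is.null(de_genes)) {
        de <- utils::read.csv(de_genes, stringsAsFactors = FALSE)
        if (!all(c("gene", "fc") %in% names(de)))
          stop("de_genes format error: need columns gene, fc", call. = FALSE)
        gene_query <- de_gene_filter(stats::setNames(de$fc, de$gene), config)
      }
      # universes are explicit choices: all profiled genes; all compounds
      # that are either annotatable here or members of a supplied pathway
      cmpd_universe <- unique(c(rownames(met),
                                unlist(lapply(pw, `[[`, "compound_members"))))
      jp <- joint_pathway_analysis(
        gene_query = gene_query,
        cmpd_query = unique(edges$metabolite),
        pathways = pw,
        gene_universe = rownames(expr),
        cmpd_universe = cmpd_universe,
        config = config, filtered = FALSE)
      counts$pathways_evaluated <- nrow(jp)
      counts$pathways_reported <- sum(jp$reported)
      results$pathways <- jp
      out$joint_pathways <- jp
    }
  }

  manifest <- write_results(
    results, out_dir, config, counts,
    inputs = unlist(Filter(Negate(is.null),
                           list(features = features, samples = samples,
                                standards = standards,
                                expression = expression,
                                pathways = pathways, topology = topology))))
  out$counts <- counts
  out$manifest <- manifest
  invisible(out)
}
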