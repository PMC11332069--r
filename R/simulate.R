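#' Generate a synthetic chiral LC-MS feature table with ground truth
#'
#' Emulates the structure of a small two-group untargeted chiral
#' metabolomics study: log-normal feature intensities, planted enantiomer
#' pairs (shared theoretical mass with ppm jitter, diastereomer RT offsets
#' inside the pairing window, unequal within-pair abundance), a planted
#' group effect on the log2 scale for a fraction of features, and a pooled
#' QC measured twice — the (+)-DATAN pool as the per-feature mean of all
#' study samples and the (-)-DATAN pool as that same pool with intensities
#' exchanged within every true pair (the idealized elution-order switch).
#' Missing values are injected completely at random into study samples.
#'
#' The returned truth records, per planted pair, both the generator's
#' target log2 abundance ratio and the *realized* ratio in the (+)-DATAN
#' pool (`log2_ratio`); the swap-verification guarantee is exact with
#' respect to the realized ratio.
#'
#' @param n_features total features (default 500).
#' @param n_pairs planted enantiomer pairs (default 100; uses
#'   `2 * n_pairs` features).
#' @param n_per_group study samples per group (default 5).
#' @param ppm_jitter_sd per-member mass jitter, ppm (default 1).
#' @param rt_offset_range min/max within-pair RT offset, minutes
#'   (default `c(0.2, 2.5)`, inside the 3-min pairing window).
#' @param log2_intensity_mean,log2_intensity_sd baseline feature abundance
#'   distribution on the log2 scale (defaults 17 and 2, typical
#'   Orbitrap-scale integrated intensities).
#' @param pair_log2_ratio_range target within-pair log2 abundance ratio
#'   (E2 over E1), drawn uniformly (default `c(1, 2.5)`).
#' @param effect_fraction fraction of features carrying a group effect
#'   (default 0.1).
#' @param effect_log2fc planted log2 fold change, positive over negative
#'   group (default 2).
#' @param noise_log2_sd per-sample measurement noise on the log2 scale
#'   (default 0.5).
#' @param missing_rate completely-at-random missingness in study samples
#'   (default 0.05).
#' @param mz_range,rt_range ranges for theoretical masses (Th) and base
#'   retention times (minutes).
#' @param ppm_pair_max planted pairs are redrawn until their realized ppm
#'   difference is strictly below this (default 5, the pairing window).
#' @param seed integer seed; the output is a pure function of the
#'   parameters and the seed.
#' @return list with `table` (a [feature_table()]) and `truth` (list:
#'   `planted_pairs`, `planted_effects`, `params`).
#' @export
generate_feature_table <- function(n_features = 500L,
                                   n_pairs = 100L,
                                   n_per_group = 5L,
                                   ppm_jitter_sd = 1,
                                   rt_offset_range = c(0.2, 2.5),
                                   log2_intensity_mean = 17,
                                   log2_intensity_sd = 2,
                                   pair_log2_ratio_range = c(1, 2.5),
                                   effect_fraction = 0.1,
                                   effect_log2fc = 2,
                                   noise_log2_sd = 0.5,
                                   missing_rate = 0.05,
                                   mz_range = c(100, 1000),
                                   rt_range = c(2, 65),
                                   ppm_pair_max = 5,
                                   seed = 42L) {
  if (2L * n_pairs > n_features)
    stop("generate_feature_table: 2 * n_pairs exceeds n_features",
         call. = FALSE)
  if (rt_offset_range[2] <= rt_offset_range[1] || rt_offset_range[1] <= 0)
    stop("generate_feature_table: invalid rt_offset_range", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("generate_feature_table: missing_rate must be in [0, 1)",
         call. = FALSE)
  set.seed(seed)
  n_single <- n_features - 2L * n_pairs
  ids <- sprintf("F%04d", seq_len(n_features))
  pair_a <- ids[seq_len(n_pairs) * 2L - 1L]
  pair_b <- ids[seq_len(n_pairs) * 2L]
  singles <- if (n_single) ids[(2L * n_pairs + 1L):n_features] else character(0)

  mz <- rt <- numeric(n_features)
  for (k in seq_len(n_pairs)) {
    m0 <- stats::runif(1, mz_range[1], mz_range[2])
    repeat {
      ma <- m0 * (1 + stats::rnorm(1, 0, ppm_jitter_sd) * 1e-6)
      mb <- m0 * (1 + stats::rnorm(1, 0, ppm_jitter_sd) * 1e-6)
      if (ma > 0 && mb > 0 && ma != mb &&
          ppm_difference(ma, mb) < ppm_pair_max) break
    }
    r0 <- stats::runif(1, rt_range[1], rt_range[2])
    off <- stats::runif(1, rt_offset_range[1], rt_offset_range[2])
    ia <- 2L * k - 1L; ib <- 2L * k
    mz[ia] <- ma; mz[ib] <- mb
    rt[ia] <- r0; rt[ib] <- r0 + off
  }
  if (n_single) {
    idx <- (2L * n_pairs + 1L):n_features
    mz[idx] <- stats::runif(n_single, mz_range[1], mz_range[2])
    rt[idx] <- stats::runif(n_single, rt_range[1], rt_range[2] + 5)
  }

  # baseline abundances; within a pair the designated low member sits
  # target_log2_ratio below the high member
  base <- stats::rnorm(n_features, log2_intensity_mean, log2_intensity_sd)
  target_ratio <- stats::runif(n_pairs, pair_log2_ratio_range[1],
                               pair_log2_ratio_range[2])
  low_is_a <- stats::runif(n_pairs) < 0.5
  for (k in seq_len(n_pairs)) {
    ia <- 2L * k - 1L; ib <- 2L * k
    hi <- base[ib]
    if (low_is_a[k]) { base[ia] <- hi - target_ratio[k] }
    else             { base[ia] <- hi; base[ib] <- hi - target_ratio[k] }
  }

  n_effect <- round(effect_fraction * n_features)
  effect_idx <- if (n_effect) sample.int(n_features, n_effect) else integer(0)
  true_l2fc <- numeric(n_features)
  true_l2fc[effect_idx] <- effect_log2fc

  groups <- c(rep("positive", n_per_group), rep("negative", n_per_group))
  snames <- c(sprintf("P%02d", seq_len(n_per_group)),
              sprintf("N%02d", seq_len(n_per_group)))
  n_study <- length(groups)
  log2m <- matrix(stats::rnorm(n_features * n_study, 0, noise_log2_sd),
                  n_features, n_study)
  log2m <- log2m + base
  log2m[, groups == "positive"] <- log2m[, groups == "positive"] + true_l2fc
  study_int <- 2^log2m

  qc_plus <- rowMeans(study_int)
  qc_minus <- qc_plus
  for (k in seq_len(n_pairs)) {
    ia <- 2L * k - 1L; ib <- 2L * k
    qc_minus[c(ia, ib)] <- qc_plus[c(ib, ia)]
  }

  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_features * n_study) < missing_rate,
                   n_features, n_study)
    study_int[drop] <- NA_real_
  }

  intensity <- cbind(study_int, QC_plus = qc_plus, QC_minus = qc_minus)
  samples <- data.frame(
    sample = c(snames, "QC_plus", "QC_minus"),
    group = c(groups, NA_character_, NA_character_),
    is_qc = c(rep(FALSE, n_study), TRUE, TRUE),
    datan_chirality = c(rep("none", n_study), "plus", "minus"),
    stringsAsFactors = FALSE
  )
  ft <- feature_table(
    data.frame(feature_id = ids, mz = mz, rt = rt, stringsAsFactors = FALSE),
    intensity, samples
  )

  e1 <- ifelse(qc_plus[match(pair_a, ids)] <= qc_plus[match(pair_b, ids)],
               pair_a, pair_b)
  e2 <- ifelse(e1 == pair_a, pair_b, pair_a)
  planted_pairs <- data.frame(
    feature_a = pair_a, feature_b = pair_b, e1 = e1, e2 = e2,
    target_log2_ratio = target_ratio,
    log2_ratio = log2(qc_plus[match(e2, ids)] / qc_plus[match(e1, ids)]),
    ppm_diff = ppm_difference(mz[match(pair_a, ids)], mz[match(pair_b, ids)]),
    rt_diff = abs(rt[match(pair_a, ids)] - rt[match(pair_b, ids)]),
    stringsAsFactors = FALSE
  )
  truth <- list(
    planted_pairs = planted_pairs,
    planted_effects = data.frame(feature_id = ids, true_log2fc = true_l2fc,
                                 stringsAsFactors = FALSE),
    params = list(n_features = n_features, n_pairs = n_pairs,
                  n_per_group = n_per_group, ppm_jitter_sd = ppm_jitter_sd,
                  rt_offset_range = rt_offset_range,
                  log2_intensity_mean = log2_intensity_mean,
                  log2_intensity_sd = log2_intensity_sd,
                  pair_log2_ratio_range = pair_log2_ratio_range,
                  effect_fraction = effect_fraction,
                  effect_log2fc = effect_log2fc,
                  noise_log2_sd = noise_log2_sd,
                  missing_rate = missing_rate, mz_range = mz_range,
                  rt_range = rt_range, ppm_pair_max = ppm_pair_max,
                  seed = seed)
  )
  list(table = ft, truth = truth)
}

#' Generate a synthetic TPM matrix with planted gene--metabolite correlations
#'
#' Planted genes are affine transforms of a metabolite abundance vector plus
#' Gaussian noise calibrated so that, conditional on the metabolite vector,
#' the population correlation equals `target_r`. Background genes are
#' independent; a stated share is constructed to fall inside the CV band
#' `(0, 0.25)` (moderate multiplicative noise around a positive mean), the
#' remainder split between high-CV and constant (CV = 0) genes.
#'
#' @param metabolite_abundances metabolites x samples numeric matrix
#'   (rownames = metabolite labels).
#' @param n_genes total genes (default 2000).
#' @param n_per_metabolite planted correlated genes per metabolite
#'   (default 20).
#' @param target_r target Pearson correlation in (0, 1) (default 0.9).
#' @param cv_band_fraction share of background genes constructed inside the
#'   CV band (default 0.3).
#' @param constant_fraction share of background genes that are constant
#'   (default 0.1).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples TPM matrix) and `truth`
#'   (list: `planted_edges`, `params`).
#' @export
generate_expression <- function(metabolite_abundances,
                                n_genes = 2000L,
                                n_per_metabolite = 20L,
                                target_r = 0.9,
                                cv_band_fraction = 0.3,
                                constant_fraction = 0.1,
                                seed = 42L) {
  if (target_r <= 0 || target_r >= 1)
    stop("generate_expression: target_r must be in (0, 1)", call. = FALSE)
  met <- as.matrix(metabolite_abundances)
  n_s <- ncol(met)
  n_met <- nrow(met)
  n_planted <- n_met * n_per_metabolite
  if (n_planted > n_genes)
    stop("generate_expression: planted genes exceed n_genes", call. = FALSE)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  expr <- matrix(0, n_genes, n_s,
                 dimnames = list(genes, colnames(met)))
  edges <- list()
  g <- 0L
  for (m in seq_len(n_met)) {
    v <- met[m, ]
    for (j in seq_len(n_per_metabolite)) {
      g <- g + 1L
      # affine-map the metabolite to a TPM-like scale whose CV lands inside
      # the (0, 0.25) filter band (Pearson r is affine-invariant), then add
      # noise sized for the target conditional correlation
      cv_g <- stats::runif(1, 0.10, 0.18)
      base <- 100 + 100 * cv_g * (v - mean(v)) / stats::sd(v)
      sigma <- stats::sd(base) * sqrt(1 / target_r^2 - 1)
      expr[g, ] <- pmax(0, base + stats::rnorm(n_s, 0, sigma))
    }
    edges[[m]] <- data.frame(
      gene = genes[(g - n_per_metabolite + 1L):g],
      metabolite = rownames(met)[m],
      target_r = target_r, stringsAsFactors = FALSE)
  }
  n_bg <- n_genes - n_planted
  n_band <- round(cv_band_fraction * n_bg)
  n_const <- round(constant_fraction * n_bg)
  n_high <- n_bg - n_band - n_const
  bg <- n_planted
  if (n_band) for (i in seq_len(n_band)) {
    bg <- bg + 1L
    mu <- stats::runif(1, 20, 200)
    expr[bg, ] <- pmax(0, mu * (1 + stats::rnorm(n_s, 0, stats::runif(1, 0.05, 0.2))))
  }
  if (n_const) for (i in seq_len(n_const)) {
    bg <- bg + 1L
    expr[bg, ] <- stats::runif(1, 1, 50)
  }
  if (n_high) for (i in seq_len(n_high)) {
    bg <- bg + 1L
    mu <- stats::runif(1, 1, 100)
    expr[bg, ] <- pmax(0, mu * (1 + stats::rnorm(n_s, 0, stats::runif(1, 0.4, 1))))
  }
  truth <- list(planted_edges = do.call(rbind, edges),
                params = list(n_genes = n_genes,
                              n_per_metabolite = n_per_metabolite,
                              target_r = target_r,
                              cv_band_fraction = cv_band_fraction,
                              constant_fraction = constant_fraction,
                              seed = seed))
  list(expr = expr, truth = truth)
}

#' Generate synthetic pathway definitions
#'
#' Random member sets over supplied gene/compound universes with optional
#' random-graph topology; planted "enriched" pathways over-sample their
#' members from supplied planted gene and compound lists.
#'
#' @param gene_universe,cmpd_universe background identifier pools.
#' @param planted_genes,planted_cmpds identifiers the enriched pathways
#'   over-sample from.
#' @param n_pathways total pathways (default 20).
#' @param n_enriched planted enriched pathways (default 2).
#' @param size_range members per pathway (default `c(10, 40)`).
#' @param enriched_share fraction of an enriched pathway's members drawn
#'   from the planted lists (default 0.8).
#' @param edge_prob topology edge probability (Erdos-Renyi; default 0.25;
#'   `NA` for no topology).
#' @param seed integer seed.
#' @return Named list of pathway definitions (see [read_gmt()]); enriched
#'   pathway ids carry the prefix `"ENR"`.
#' @export
generate_pathways <- function(gene_universe, cmpd_universe,
                              planted_genes = character(),
                              planted_cmpds = character(),
                              n_pathways = 20L, n_enriched = 2L,
                              size_range = c(10L, 40L),
                              enriched_share = 0.8,
                              edge_prob = 0.25,
                              seed = 42L) {
  set.seed(seed)
  pw <- list()
  for (i in seq_len(n_pathways)) {
    enriched <- i <= n_enriched && length(planted_genes) && length(planted_cmpds)
    pid <- if (enriched) sprintf("ENR%02d", i) else sprintf("PW%02d", i)
    size <- sample(size_range[1]:size_range[2], 1L)
    n_cmpd <- max(1L, round(size * 0.25))
    n_gene <- size - n_cmpd
    if (enriched) {
      ng_pl <- min(length(planted_genes), round(enriched_share * n_gene))
      nc_pl <- min(length(planted_cmpds), round(enriched_share * n_cmpd))
      gm <- unique(c(sample(planted_genes, ng_pl),
                     sample(gene_universe, n_gene - ng_pl)))
      cm <- unique(c(sample(planted_cmpds, nc_pl),
                     sample(cmpd_universe, n_cmpd - nc_pl)))
    } else {
      gm <- sample(gene_universe, min(n_gene, length(gene_universe)))
      cm <- sample(cmpd_universe, min(n_cmpd, length(cmpd_universe)))
    }
    topo <- NULL
    if (!is.na(edge_prob)) {
      members <- c(gm, cm)
      cmb <- utils::combn(members, 2L)
      keep <- stats::runif(ncol(cmb)) < edge_prob
      topo <- data.frame(node_a = cmb[1L, keep], node_b = cmb[2L, keep],
                         stringsAsFactors = FALSE)
    }
    pw[[pid]] <- validate_pathway(list(
      pathway_id = pid,
      name = if (enriched) paste0("planted enriched pathway ", i)
             else paste0("background pathway ", i),
      gene_members = gm, compound_members = cm, topology = topo))
  }
  pw
}

#' Write / read a synthetic ground-truth file
#'
#' Truth files are JSON and round-trip losslessly; they are sufficient to
#' score pair recovery, effect recovery, edge recovery and enrichment
#' ranking without re-reading generator internals.
#'
#' @param truth list of truth components (data.frames and parameter lists).
#' @param path JSON path.
#' @return `read_truth()` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(tr)) {
    if (is.list(tr[[nm]]) && !is.null(tr[[nm]]$feature_a))
      tr[[nm]] <- as.data.frame(tr[[nm]], stringsAsFactors = FALSE)
  }
  tr
}

#' Simulate a complete study to disk
#'
#' Writes the paper-like synthetic preset — feature table, sample sheet,
#' expression matrix, standards library, pathway sets (GMT + edge-list
#' topology) and ground-truth JSON — into a directory, ready for
#' [run_pipeline()].
#'
#' The standards library is constructed from the first planted pairs so
#' that annotation has exact matches: five named amino acids carry D/L
#' labels (lower-abundance member = D, mirroring the convention that the
#' minor enantiomer is the rarer D form in these data), the next pairs are
#' E1/E2 unknowns, and a handful of singleton features become achiral
#' standards.
#'
#' @param dir output directory.
#' @param seed integer seed driving every generator.
#' @param ... overrides passed to [generate_feature_table()].
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   objects (`table`, `truth`, `expr`, `expr_truth`, `pathways`).
#' @export
simulate_study <- function(dir, seed = 42L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_feature_table(seed = seed, ...)
  ft <- sim$table
  pp <- sim$truth$planted_pairs

  named <- c("glutamine", "asparagine", "leucine", "valine", "phenylalanine")
  n_named <- min(length(named), nrow(pp))
  lib <- list()
  for (k in seq_len(n_named)) {
    i1 <- match(pp$e1[k], ft$features$feature_id)
    i2 <- match(pp$e2[k], ft$features$feature_id)
    lib[[length(lib) + 1L]] <- data.frame(
      compound = named[k], enantiomer = c("D", "L"),
      expected_mz = ft$features$mz[c(i1, i2)],
      expected_rt = ft$features$rt[c(i1, i2)], stringsAsFactors = FALSE)
  }
  n_unk <- min(5L, nrow(pp) - n_named)
  for (k in seq_len(n_unk)) {
    kk <- n_named + k
    i1 <- match(pp$e1[kk], ft$features$feature_id)
    i2 <- match(pp$e2[kk], ft$features$feature_id)
    lib[[length(lib) + 1L]] <- data.frame(
      compound = paste0("unknown-", k), enantiomer = c("E1", "E2"),
      expected_mz = ft$features$mz[c(i1, i2)],
      expected_rt = ft$features$rt[c(i1, i2)], stringsAsFactors = FALSE)
  }
  singles <- setdiff(ft$features$feature_id, c(pp$feature_a, pp$feature_b))
  n_ach <- min(5L, length(singles))
  if (n_ach) {
    idx <- match(singles[seq_len(n_ach)], ft$features$feature_id)
    lib[[length(lib) + 1L]] <- data.frame(
      compound = paste0("achiral-", seq_len(n_ach)), enantiomer = "achiral",
      expected_mz = ft$features$mz[idx],
      expected_rt = ft$features$rt[idx], stringsAsFactors = FALSE)
  }
  standards <- validate_standards(do.call(rbind, lib))

  # metabolite abundances for the correlation stage: D-form (e1) of the
  # named amino acids over the positive-group samples
  pos <- study_samples(ft, "positive")
  met <- ft$intensity[match(pp$e1[seq_len(n_named)], ft$features$feature_id),
                      pos, drop = FALSE]
  if (anyNA(met)) {  # complete-case the metabolite vectors with row means
    rm_ <- rowMeans(met, na.rm = TRUE)
    for (r_ in seq_len(nrow(met))) met[r_, is.na(met[r_, ])] <- rm_[r_]
  }
  rownames(met) <- paste0("D-", named[seq_len(n_named)])
  ex <- generate_expression(met, seed = seed + 1L)
  # compound universe: annotatable compounds plus a background compound pool,
  # so pathway compound enrichment is non-degenerate
  cmpd_bg <- sprintf("cmpd-%03d", seq_len(80L))
  pw <- generate_pathways(
    gene_universe = rownames(ex$expr),
    cmpd_universe = c(as.vector(outer(c("D-", "L-"), named, paste0)),
                      paste0("achiral-", seq_len(max(n_ach, 1L))), cmpd_bg),
    planted_genes = ex$truth$planted_edges$gene,
    planted_cmpds = paste0("D-", named[seq_len(n_named)]),
    seed = seed + 2L)

  paths <- list(
    features = file.path(dir, "features.tsv"),
    samples = file.path(dir, "samples.csv"),
    expression = file.path(dir, "expression.tsv"),
    standards = file.path(dir, "standards.csv"),
    pathways = file.path(dir, "pathways.gmt"),
    topology = file.path(dir, "topology.tsv"),
    truth_file = file.path(dir, "truth.json")
  )
  write_feature_table(ft, paths$features, paths$samples)
  write_expression(ex$expr, paths$expression)
  utils::write.csv(standards, paths$standards, row.names = FALSE, quote = FALSE)
  write_gmt(pw, paths$pathways, paths$topology)
  write_truth(c(sim$truth, list(planted_edges = ex$truth$planted_edges)),
              paths$truth_file)
  invisible(c(paths, list(table = ft, truth = sim$truth, expr = ex$expr,
                          expr_truth = ex$truth, pathways = pw,
                          standards = standards)))
}
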