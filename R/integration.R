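#' Coefficient-of-variation gene filter
#'
#' CV = sample standard deviation (n-1 denominator) / mean, per gene. Genes
#' are kept when `cv_lo < CV < cv_hi` (strict on both sides): the lower
#' bound removes flat/uninformative genes, the upper bound removes genes
#' whose expression is dominated by patient-specific variation. Genes with
#' mean 0 are excluded.
#'
#' @param expr genes x samples numeric matrix (TPM) with rownames.
#' @param config an [analysis_config()].
#' @return Character vector of retained gene symbols; the per-gene CVs are
#'   attached as attribute `"cv"`.
#' @export
cv_filter <- function(expr, config = analysis_config()) {
  if (ncol(expr) < 2L)
    stop("cv_filter: need >= 2 samples to compute a CV", call. = FALSE)
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  keep <- !is.na(cv) & cv > config$cv_lo & cv < config$cv_hi
  out <- rownames(expr)[keep]
  attr(out, "cv") <- stats::setNames(cv, rownames(expr))
  out
}

#' Fold-change gene filter
#'
#' Keeps genes whose linear fold change strictly exceeds
#' `gene_fc_threshold`; in absolute mode (default) genes below the
#' reciprocal `1/gene_fc_threshold` are kept too.
#'
#' @param fold_changes named numeric vector of linear fold changes.
#' @param config an [analysis_config()].
#' @return Character vector of retained gene symbols.
#' @export
de_gene_filter <- function(fold_changes, config = analysis_config()) {
  fc <- fold_changes[is.finite(fold_changes)]
  thr <- config$gene_fc_threshold
  keep <- fc > thr
  if (config$gene_fc_absolute) keep <- keep | fc < 1 / thr
  names(fc)[keep]
}

#' Gene--metabolite Pearson correlation edges
#'
#' Computes the product-moment correlation between every gene row and every
#' metabolite abundance vector over matched samples and emits an edge for
#' each pair with `r >= r_min` (positive correlations only). Zero-variance
#' genes or metabolites yield no edge and are reported via `message()`.
#'
#' @param expr genes x samples matrix (already CV-filtered, typically).
#' @param metabolites metabolites x samples matrix (rownames = metabolite
#'   labels, e.g. `"D-glutamine"`), columns matching `expr` sample order.
#' @param config an [analysis_config()].
#' @return data.frame (`CorrelationEdge`): `gene`, `metabolite`, `r`, `n`.
#' @export
correlate <- function(expr, metabolites, config = analysis_config()) {
  if (ncol(expr) != ncol(metabolites))
    stop("correlate: sample counts differ between matrices", call. = FALSE)
  n <- ncol(expr)
  if (n < 3L) stop("correlate: need n >= 3 samples", call. = FALSE)
  degen_g <- apply(expr, 1L, stats::sd) == 0
  degen_m <- apply(metabolites, 1L, stats::sd) == 0
  if (any(degen_g))
    message("correlate: ", sum(degen_g),
            " zero-variance gene(s) skipped (r undefined)")
  if (any(degen_m))
    message("correlate: ", sum(degen_m),
            " zero-variance metabolite(s) skipped (r undefined)")
  r <- stats::cor(t(expr[!degen_g, , drop = FALSE]),
                  t(metabolites[!degen_m, , drop = FALSE]))
  hit <- which(r >= config$r_min, arr.ind = TRUE)
  out <- data.frame(gene = rownames(r)[hit[, 1L]],
                    metabolite = colnames(r)[hit[, 2L]],
                    r = r[hit], n = n, stringsAsFactors = FALSE)
  out[order(out$metabolite, -out$r, out$gene), , drop = FALSE]
}

#' Overlap of correlated genes with pathway gene sets
#'
#' For each metabolite, intersects its positively correlated genes with the
#' union of the pathways' gene members, and lists, per overlapping gene, the
#' pathways that contain it.
#'
#' @param edges a [correlate()] data.frame.
#' @param pathways list of pathway definitions ([read_gmt()]).
#' @return data.frame: `metabolite`, `gene`, `pathways`
#'   (semicolon-separated pathway ids).
#' @export
overlap_with_pathway_genes <- function(edges, pathways) {
  pw_genes <- lapply(pathways, `[[`, "gene_members")
  union_genes <- unique(unlist(pw_genes))
  out <- list()
  for (met in unique(edges$metabolite)) {
    g <- intersect(edges$gene[edges$metabolite == met], union_genes)
    if (!length(g)) next
    supp <- vapply(g, function(gi) {
      paste(names(pathways)[vapply(pw_genes, function(m) gi %in% m,
                                   logical(1))], collapse = ";")
    }, character(1))
    out[[met]] <- data.frame(metabolite = met, gene = g,
                             pathways = unname(supp),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(metabolite = character(), gene = character(),
                      pathways = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing `k = |query n members|`
#' members when `|query|` items are drawn without replacement from
#' `universe`.
#'
#' @param query character vector (the hit list), a subset of `universe`.
#' @param members pathway member set, a subset of `universe`.
#' @param universe background set.
#' @return p-value in (0, 1].
#' @export
hypergeometric_enrichment <- function(query, members, universe) {
  query <- unique(query); members <- unique(members); universe <- unique(universe)
  stray <- setdiff(members, universe)
  if (length(stray))
    stop("hypergeometric_enrichment: member '", stray[1L],
         "' outside universe", call. = FALSE)
  stray <- setdiff(query, universe)
  if (length(stray))
    stop("hypergeometric_enrichment: query item '", stray[1L],
         "' outside universe", call. = FALSE)
  k <- length(intersect(query, members))
  stats::phyper(k - 1L, length(members), length(universe) - length(members),
                length(query), lower.tail = FALSE)
}

#' Fisher's unweighted combination of p-values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. A single p-value is returned unchanged.
#'
#' @param p_values numeric vector, each in (0, 1].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("fisher_combine: no p-values", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1))
    stop("fisher_combine: p-values must lie in (0, 1]", call. = FALSE)
  if (length(p_values) == 1L) return(p_values)
  stats::pchisq(-2 * sum(log(p_values)), df = 2 * length(p_values),
                lower.tail = FALSE)
}

#' Degree-centrality pathway impact
#'
#' Fraction of total node degree carried by the hit nodes:
#' `sum(degree(hits)) / sum(degree(all members))`, in [0, 1]. Pathways
#' without a topology fall back to the complete-graph assumption (all
#' degrees equal), i.e. `|hits| / |members|`, and the result is flagged
#' via attribute `"complete_graph"`.
#'
#' @param pathway one pathway definition ([read_gmt()]).
#' @param hit_nodes character vector of hit members (genes and/or
#'   compounds).
#' @return Impact in [0, 1].
#' @export
topology_impact <- function(pathway, hit_nodes) {
  members <- c(pathway$gene_members, pathway$compound_members)
  if (!length(members))
    stop("topology_impact: pathway '", pathway$pathway_id,
         "' has no members", call. = FALSE)
  stray <- setdiff(hit_nodes, members)
  if (length(stray))
    stop("topology_impact: hit node '", stray[1L], "' is not a member of '",
         pathway$pathway_id, "'", call. = FALSE)
  if (is.null(pathway$topology) || !nrow(pathway$topology)) {
    imp <- length(unique(hit_nodes)) / length(members)
    attr(imp, "complete_graph") <- TRUE
    return(imp)
  }
  nodes <- c(pathway$topology$node_a, pathway$topology$node_b)
  deg <- table(factor(nodes, levels = members))
  total <- sum(deg)
  imp <- if (total == 0) 0 else sum(deg[unique(hit_nodes)]) / total
  attr(imp, "complete_graph") <- FALSE
  imp
}

#' Joint metabolite--gene pathway analysis
#'
#' For each pathway, tests the gene hit list and the compound hit list by
#' separate hypergeometric tests over their respective universes, combines
#' the available p-values by Fisher's unweighted method (a test is included
#' only when the pathway has members of that type inside the universe), and
#' scores topology impact from the union of hit nodes. The filtered report
#' keeps pathways with at least one compound hit, at least one gene hit,
#' `p_combined < alpha` and `impact > impact_min`.
#'
#' @param gene_query character vector of selected genes.
#' @param cmpd_query character vector of selected compounds.
#' @param pathways list of pathway definitions.
#' @param gene_universe,cmpd_universe background sets (explicit inputs:
#'   enrichment p-values depend on them).
#' @param config an [analysis_config()].
#' @param filtered return only the filtered report (default) or all
#'   evaluated pathways.
#' @return data.frame (`JointPathwayResult`): `pathway_id`, `name`,
#'   `total`, `hits_cmpd`, `hits_gene`, `p_gene`, `p_cmpd`, `p_combined`,
#'   `impact`, `complete_graph`, `reported`.
#' @export
joint_pathway_analysis <- function(gene_query, cmpd_query, pathways,
                                   gene_universe, cmpd_universe,
                                   config = analysis_config(),
                                   filtered = TRUE) {
  gene_query <- intersect(unique(gene_query), gene_universe)
  cmpd_query <- intersect(unique(cmpd_query), cmpd_universe)
  rows <- lapply(pathways, function(p) {
    gm <- intersect(p$gene_members, gene_universe)
    cm <- intersect(p$compound_members, cmpd_universe)
    gh <- intersect(gene_query, gm)
    ch <- intersect(cmpd_query, cm)
    ps <- c(gene = if (length(gm)) hypergeometric_enrichment(gene_query, gm, gene_universe),
            cmpd = if (length(cm)) hypergeometric_enrichment(cmpd_query, cm, cmpd_universe))
    p_comb <- if (length(ps)) fisher_combine(unname(ps)) else NA_real_
    hits <- c(gh, ch)
    imp <- topology_impact(p, hits)
    data.frame(pathway_id = p$pathway_id, name = p$name,
               total = length(p$gene_members) + length(p$compound_members),
               hits_cmpd = length(ch), hits_gene = length(gh),
               p_gene = if ("gene" %in% names(ps)) ps[["gene"]] else NA_real_,
               p_cmpd = if ("cmpd" %in% names(ps)) ps[["cmpd"]] else NA_real_,
               p_combined = p_comb,
               impact = as.numeric(imp),
               complete_graph = isTRUE(attr(imp, "complete_graph")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$reported <- res$hits_cmpd >= 1 & res$hits_gene >= 1 &
    !is.na(res$p_combined) & res$p_combined < config$alpha &
    res$impact > config$impact_min
  res <- res[order(res$p_combined), , drop = FALSE]
  if (filtered) res[res$reported, , drop = FALSE] else res
}
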