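# integration: CV filter, DE filter, correlation edges, overlap,
# hypergeometric enrichment, Fisher combination, topology impact,
# joint pathway analysis

test_that("CV filter uses strict bounds and n-1 standard deviation", {
  expr <- rbind(
    constant = rep(5, 5),              # CV = 0 -> excluded
    wide = c(1, 1, 1, 1, 2),           # CV ~ 0.3727 -> excluded
    tight = c(10, 10.5, 9.5, 10, 10),  # CV ~ 0.0354 -> retained
    zero = rep(0, 5)                   # mean 0 -> excluded
  )
  kept <- cv_filter(expr)
  expect_identical(as.character(kept), "tight")
  cv <- attr(kept, "cv")
  expect_equal(unname(cv["wide"]), sqrt(0.2) / 1.2, tolerance = 1e-12)
  expect_equal(unname(cv["tight"]), sd(expr["tight", ]) / 10,
               tolerance = 1e-12)
  expect_error(cv_filter(expr[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("DE gene filter is strict and reciprocal in absolute mode", {
  fc <- c(up = 1.6, at = 1.5, down = 0.5, mid = 1.0, big = 3)
  expect_setequal(de_gene_filter(fc), c("up", "down", "big"))
  cfg_signed <- analysis_config(gene_fc_absolute = FALSE)
  expect_setequal(de_gene_filter(fc, cfg_signed), c("up", "big"))

  set.seed(41)
  fcs <- stats::setNames(exp(rnorm(100)), sprintf("g%03d", 1:100))
  loop <- names(fcs)[sapply(fcs, function(v) v > 1.5 || v < 1 / 1.5)]
  expect_setequal(de_gene_filter(fcs), loop)
})

test_that("correlation edges: perfect line, sign rule, loop oracle", {
  met <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("D-met", NULL))
  expr <- rbind(lin = 2 * met[1, ] + 1, neg = -met[1, ])
  e <- correlate(expr, met)
  expect_identical(e$gene, "lin")
  expect_equal(e$r, 1.0)

  set.seed(42)
  expr2 <- matrix(rnorm(50 * 5), 50, 5,
                  dimnames = list(sprintf("g%02d", 1:50), NULL))
  mets2 <- matrix(rlnorm(3 * 5), 3, 5,
                  dimnames = list(c("m1", "m2", "m3"), NULL))
  cfg_all <- analysis_config(r_min = -1.1)  # keep every edge for comparison
  e2 <- correlate(expr2, mets2, cfg_all)
  for (k in sample(nrow(e2), 20)) {
    expect_equal(e2$r[k],
                 oracle_pearson(expr2[e2$gene[k], ], mets2[e2$metabolite[k], ]),
                 tolerance = 1e-12)
  }
  # symmetric under joint permutation of samples
  perm <- sample(5)
  e2p <- correlate(expr2[, perm], mets2[, perm], cfg_all)
  expect_equal(e2p[order(e2p$gene, e2p$metabolite), "r"],
               e2[order(e2$gene, e2$metabolite), "r"], tolerance = 1e-12)
})

test_that("zero-variance rows give no edge, with a log message", {
  met <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("m", NULL))
  expr <- rbind(flat = rep(3, 5), lin = met[1, ])
  expect_message(e <- correlate(expr, met), "zero-variance")
  expect_identical(e$gene, "lin")
})

test_that("pathway-gene overlap is a per-metabolite intersection", {
  edges <- data.frame(gene = c("G1", "G2", "G9"),
                      metabolite = c("m", "m", "other"), r = 0.9, n = 5)
  pw <- list(P1 = list(pathway_id = "P1", name = "p", gene_members = c("G2", "G3"),
                       compound_members = character(), topology = NULL),
             P2 = list(pathway_id = "P2", name = "q", gene_members = c("G2", "G4"),
                       compound_members = character(), topology = NULL))
  ov <- overlap_with_pathway_genes(edges, pw)
  expect_equal(nrow(ov), 1L)
  expect_identical(ov$gene, "G2")
  expect_identical(ov$pathways, "P1;P2")
  # disjoint -> empty
  ov2 <- overlap_with_pathway_genes(
    data.frame(gene = "GX", metabolite = "m", r = 0.9, n = 5), pw)
  expect_equal(nrow(ov2), 0L)
})

test_that("hypergeometric enrichment: hand combinatorics and enumeration", {
  u <- sprintf("u%02d", 1:10)
  expect_equal(hypergeometric_enrichment(u[1:5], u[1:5], u), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(character(0), u[1:5], u), 1)
  expect_error(hypergeometric_enrichment(u[1:2], c(u[1:2], "zz"), u),
               "outside universe")

  set.seed(43)
  for (rep in 1:10) {
    n_u <- sample(8:15, 1)
    u2 <- sprintf("v%02d", seq_len(n_u))
    m <- sample(2:(n_u - 2), 1)
    q <- sample(2:(n_u - 2), 1)
    query <- sample(u2, q)
    members <- u2[seq_len(m)]
    k <- length(intersect(query, members))
    expect_equal(hypergeometric_enrichment(query, members, u2),
                 oracle_hyper_enum(k, m, n_u, q), tolerance = 1e-12)
  }
})

test_that("hypergeometric p is monotone in the overlap", {
  u <- sprintf("u%02d", 1:20)
  members <- u[1:8]
  p_prev <- 1.01
  for (k in 0:6) {
    query <- c(u[seq_len(k)], u[9:(14 - k)])  # size 6, overlap k
    p <- hypergeometric_enrichment(query, members, u)
    expect_lt(p, p_prev + 1e-15)
    p_prev <- p
  }
})

test_that("Fisher combination: boundaries, identity, chi-square oracle", {
  expect_equal(fisher_combine(c(1, 1)), 1.0)
  expect_equal(fisher_combine(0.037), 0.037)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-2 * 2 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0175, tolerance = 1e-2)
  # permutation invariance
  set.seed(44)
  p <- runif(5)
  expect_equal(fisher_combine(p), fisher_combine(rev(p)), tolerance = 1e-15)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("topology impact: star graph, bounds, complete-graph fallback", {
  star <- validate_pathway(list(
    pathway_id = "S", name = "star",
    gene_members = c("hub", "a", "b", "c", "d"),
    compound_members = character(),
    topology = data.frame(node_a = "hub", node_b = c("a", "b", "c", "d"))))
  expect_equal(as.numeric(topology_impact(star, "hub")), 0.5)  # 4 / 8
  expect_equal(as.numeric(topology_impact(star, star$gene_members)), 1.0)
  expect_equal(as.numeric(topology_impact(star, character(0))), 0.0)
  expect_equal(as.numeric(topology_impact(star, "a")), 1 / 8)

  flat <- list(pathway_id = "F", name = "flat",
               gene_members = c("x", "y", "z", "w"),
               compound_members = character(), topology = NULL)
  imp <- topology_impact(flat, c("x", "y"))
  expect_equal(as.numeric(imp), 0.5)
  expect_true(attr(imp, "complete_graph"))
  expect_error(topology_impact(star, "nope"), "not a member")
})

test_that("joint pathway analysis equals hand-chained oracle calls", {
  gene_u <- sprintf("G%02d", 1:40)
  cmpd_u <- sprintf("C%02d", 1:15)
  set.seed(45)
  pw <- list()
  for (i in 1:5) {
    gm <- sample(gene_u, 8); cm <- sample(cmpd_u, 4)
    pw[[paste0("P", i)]] <- list(
      pathway_id = paste0("P", i), name = paste0("path ", i),
      gene_members = gm, compound_members = cm, topology = NULL)
  }
  gene_q <- sample(gene_u, 12); cmpd_q <- sample(cmpd_u, 5)
  res <- joint_pathway_analysis(gene_q, cmpd_q, pw, gene_u, cmpd_u,
                                filtered = FALSE)
  expect_equal(nrow(res), 5L)
  for (i in 1:5) {
    p <- pw[[paste0("P", i)]]
    row <- res[res$pathway_id == p$pathway_id, ]
    pg <- hypergeometric_enrichment(gene_q, p$gene_members, gene_u)
    pc <- hypergeometric_enrichment(cmpd_q, p$compound_members, cmpd_u)
    expect_equal(row$p_gene, pg, tolerance = 1e-12)
    expect_equal(row$p_cmpd, pc, tolerance = 1e-12)
    expect_equal(row$p_combined, fisher_combine(c(pg, pc)), tolerance = 1e-12)
    hits <- c(intersect(gene_q, p$gene_members),
              intersect(cmpd_q, p$compound_members))
    expect_equal(row$impact, length(hits) / 12, tolerance = 1e-12)
    expect_identical(row$reported,
                     row$hits_cmpd >= 1 && row$hits_gene >= 1 &&
                       row$p_combined < 0.05 && row$impact > 0.2)
  }
})

test_that("pathways without compound members are excluded from the report", {
  gene_u <- sprintf("G%02d", 1:10)
  cmpd_u <- sprintf("C%02d", 1:10)
  pw <- list(G_only = list(pathway_id = "G_only", name = "genes only",
                           gene_members = gene_u[1:3],
                           compound_members = character(), topology = NULL))
  res <- joint_pathway_analysis(gene_u[1:3], cmpd_u[1:3], pw, gene_u, cmpd_u,
                                filtered = FALSE)
  expect_true(is.na(res$p_cmpd))
  expect_equal(res$p_combined, res$p_gene)  # only the gene test combined
  expect_false(res$reported)
  expect_equal(nrow(joint_pathway_analysis(gene_u[1:3], cmpd_u[1:3], pw,
                                           gene_u, cmpd_u)), 0L)
})
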