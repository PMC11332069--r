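# Independent oracles: deliberately naive loop/enumeration implementations,
# kept free of any package internals they are used to check.

# Greedy matching by repeated global-minimum selection over an explicit
# all-pairs candidate list.
oracle_pairing <- function(features, ppm_max = 5, rt_max = 3) {
  n <- nrow(features)
  cand <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ppm <- abs(features$mz[i] - features$mz[j]) /
      ((features$mz[i] + features$mz[j]) / 2) * 1e6
    drt <- abs(features$rt[i] - features$rt[j])
    if (ppm < ppm_max && drt > 0 && drt < rt_max) {
      a <- min(features$feature_id[i], features$feature_id[j])
      b <- max(features$feature_id[i], features$feature_id[j])
      cand <- rbind(cand, data.frame(feature_a = a, feature_b = b,
                                     ppm_diff = ppm, rt_diff = drt))
    }
  }
  out <- NULL
  while (!is.null(cand) && nrow(cand)) {
    o <- order(cand$ppm_diff, cand$rt_diff, cand$feature_a, cand$feature_b)
    best <- cand[o[1L], ]
    out <- rbind(out, best)
    keep <- !(cand$feature_a %in% c(best$feature_a, best$feature_b) |
                cand$feature_b %in% c(best$feature_a, best$feature_b))
    cand <- cand[keep, , drop = FALSE]
  }
  if (is.null(out))
    out <- data.frame(feature_a = character(), feature_b = character(),
                      ppm_diff = numeric(), rt_diff = numeric())
  rownames(out) <- NULL
  out[order(out$feature_a), , drop = FALSE]
}

# Element-wise PQN factors: median of per-feature quotients vs the median
# reference, explicit loops.
oracle_pqn_factors <- function(m, study_cols) {
  ref <- numeric(nrow(m))
  for (i in seq_len(nrow(m)))
    ref[i] <- median(m[i, study_cols], na.rm = TRUE)
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    q <- c()
    for (i in seq_len(nrow(m)))
      if (!is.na(m[i, j]) && !is.na(ref[i]) && ref[i] > 0)
        q <- c(q, m[i, j] / ref[i])
    f[j] <- median(q)
  }
  f
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free inputs).
oracle_wilcoxon_enum <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); n1 <- length(x)
  r_obs <- sum(rank(all_v)[seq_len(n1)])
  idx <- utils::combn(n, n1)
  rk <- rank(all_v)
  sums <- apply(idx, 2L, function(ii) sum(rk[ii]))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(r_obs - mu) - 1e-12)
}

# Hypergeometric upper tail by enumeration of all possible draws.
oracle_hyper_enum <- function(k, m, n_univ, q) {
  idx <- utils::combn(n_univ, q)
  # items 1..m are "members"
  overlaps <- apply(idx, 2L, function(ii) sum(ii <= m))
  mean(overlaps >= k)
}

# Definitional Pearson correlation, explicit loop.
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# Small labeled feature table built in code, for unit tests.
toy_table <- function(intensity, mz = NULL, rt = NULL,
                      groups = NULL, qc = NULL) {
  n_f <- nrow(intensity); n_s <- ncol(intensity)
  if (is.null(mz)) mz <- seq(100, by = 50, length.out = n_f)
  if (is.null(rt)) rt <- seq(1, by = 2, length.out = n_f)
  if (is.null(groups))
    groups <- rep(c("positive", "negative"), length.out = n_s)
  if (is.null(qc)) qc <- rep("none", n_s)
  is_qc <- qc != "none"
  feature_table(
    data.frame(feature_id = sprintf("F%03d", seq_len(n_f)), mz = mz, rt = rt),
    intensity,
    data.frame(sample = sprintf("S%02d", seq_len(n_s)),
               group = ifelse(is_qc, NA_character_, groups),
               is_qc = is_qc, datan_chirality = qc)
  )
}
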