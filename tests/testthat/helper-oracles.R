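# Independent oracles and small fixture builders shared across tests.

# Direct-summation ssGSEA oracle: one gene at a time down the ranking,
# accumulating the weighted in-set ECDF minus the uniform out-of-set ECDF.
# Deliberately loop-based and independent of the vectorized engine.
ssgsea_oracle_one <- function(values, gene_names, set_genes, alpha = 0.25) {
  r <- rank(values, ties.method = "average")
  names(r) <- gene_names
  walk <- gene_names[order(-r, seq_along(r))]
  in_set <- walk %in% set_genes
  denom_in <- sum(r[set_genes[set_genes %in% gene_names]]^alpha)
  n_out <- length(walk) - sum(in_set)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_along(walk)) {
    if (in_set[i]) p_in <- p_in + r[walk[i]]^alpha / denom_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

ssgsea_oracle <- function(expr, sets, alpha = 0.25) {
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr)))
    for (s in seq_along(sets))
      out[s, j] <- ssgsea_oracle_one(expr[, j], rownames(expr),
                                     sets[[s]], alpha)
  out
}

# Vectorized one-way ANOVA F-test p-values, one per gene row.
anova_p_per_gene <- function(expr, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- ncol(expr)
  gm <- rowMeans(expr)
  ssb <- 0; ssw <- 0
  for (lv in levels(g)) {
    sel <- g == lv
    m <- rowMeans(expr[, sel, drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + rowSums((expr[, sel, drop = FALSE] - m)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Small well-separated planted fixture used by several clustering tests.
small_planted_fixture <- function(seed = 11L, n = 100L, sep = 3) {
  synthetic_dataset(synthetic_config(
    n_samples = n, n_regulator_genes = 50L, n_noise_genes = 52L,
    pattern_separation = sep,
    immune_sets = list(
      list(name = "imm1", size = 24L, shift = c(0, 1, 2)),
      list(name = "imm2", size = 24L, shift = c(2, 0, 1))),
    seed = seed))
}

# cross-test cache so the expensive planted fixture is built once
.acc_cache <- new.env(parent = emptyenv())

expect_same_partition <- function(a, b) {
  expect_equal(adjusted_rand_index(a, b), 1)
}
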