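# Noise filtering and the two-cohort differential-regulator screen.
# Differential expression on log-scale values uses a per-gene Welch t test
# with Benjamini-Hochberg adjustment; cohort-specific significance cutoffs
# are intersected to produce the hub-regulator list.

#' Filter low-variability genes by median absolute deviation
#'
#' Computes the unscaled MAD (median of absolute deviations from the gene
#' median, no consistency constant) per gene and drops genes with
#' MAD <= threshold. Gene order is preserved.
#'
#' @param expr genes x samples numeric matrix.
#' @param threshold genes with MAD at or below this value are removed.
#' @return the filtered matrix.
#' @export
mad_filter <- function(expr, threshold = 0.5) {
  stopifnot(is.matrix(expr), nrow(expr) > 0)
  mads <- apply(expr, 1L, mad, constant = 1)
  keep <- mads > threshold
  if (!any(keep))
    stop("mad_filter removed every gene; review the threshold (",
         threshold, ")")
  expr[keep, , drop = FALSE]
}

#' Two-group differential expression (Welch t on log-scale values)
#'
#' Per-gene Welch t test comparing group2 against group1, BH adjustment
#' across all tested genes. logFC is the difference of group means on the
#' log scale (group2 - group1). Genes with zero variance in both groups get
#' p = 1 and logFC = 0 when the means are equal (declared convention), and
#' p = 0 when they differ.
#'
#' @param expr genes x samples numeric matrix.
#' @param groups character/factor vector (or named vector keyed by sample)
#'   with exactly two levels; the second level in sort order is "group2"
#'   unless a factor supplies its own level order.
#' @return data.frame: gene, logFC, mean_group1, mean_group2, p, p_adj.
#' @export
two_group_de <- function(expr, groups) {
  stopifnot(is.matrix(expr))
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(expr), names(groups))
    if (length(missing))
      stop("groups missing for samples: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(expr)]
  }
  f <- factor(groups)
  if (nlevels(f) != 2L) stop("exactly two groups required")
  n1 <- sum(f == levels(f)[1]); n2 <- sum(f == levels(f)[2])
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")")

  x1 <- expr[, f == levels(f)[1], drop = FALSE]
  x2 <- expr[, f == levels(f)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m2 - m1

  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & lfc == 0
    p[equal] <- 1
    lfc[equal] <- 0
    p[degenerate & !equal] <- 0
  }
  res <- data.frame(gene = rownames(expr), logFC = lfc,
                    mean_group1 = m1, mean_group2 = m2,
                    p = p, p_adj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Intersect differential regulators across two cohorts
#'
#' Genes significant at the discovery-cohort cutoff in `de_a` and at the
#' testing-cohort cutoff in `de_b`, sorted lexicographically. Optionally
#' requires a consistent fold-change direction across cohorts.
#'
#' @param de_a,de_b [two_group_de()] results sharing a gene universe.
#' @param alpha_a,alpha_b cohort-specific adjusted-p cutoffs.
#' @param require_same_sign if TRUE, also require sign(logFC) to agree.
#' @return character vector of intersecting genes (possibly empty, with a
#'   warning).
#' @export
intersect_regulators <- function(de_a, de_b, alpha_a = 0.01, alpha_b = 0.05,
                                 require_same_sign = FALSE) {
  shared <- intersect(de_a$gene, de_b$gene)
  if (!length(shared)) stop("the two DE results share no genes")
  pass_a <- de_a$gene[de_a$p_adj < alpha_a]
  pass_b <- de_b$gene[de_b$p_adj < alpha_b]
  hits <- intersect(intersect(pass_a, pass_b), shared)
  if (require_same_sign && length(hits)) {
    sa <- sign(de_a$logFC[match(hits, de_a$gene)])
    sb <- sign(de_b$logFC[match(hits, de_b$gene)])
    hits <- hits[sa == sb]
  }
  if (!length(hits)) warning("empty regulator intersection")
  sort(hits)
}
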