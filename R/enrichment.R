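# Single-sample gene-set enrichment (ssGSEA). For each sample, genes are
# ranked by expression (ties get the average rank); walking down the ranking
# the enrichment score is the accumulated gap between the weighted in-set
# ECDF (rank^alpha weights) and the uniform out-of-set ECDF. One engine
# serves both the immune-cell abundance and pathway-signature analyses.

#' Single-sample gene-set enrichment scores
#'
#' @param expr genes x samples numeric matrix.
#' @param sets named list of character vectors (gene sets). Genes absent
#'   from `expr` are ignored; after intersection every set must share at
#'   least one gene with the matrix and be a proper subset of its genes.
#' @param alpha rank-weight exponent (0 = unweighted ECDF).
#' @param normalize if TRUE, divide all scores by the global
#'   (max - min) of the score matrix.
#' @return sets x samples matrix of enrichment scores with a
#'   `normalized` attribute.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  genes <- rownames(expr)
  n_genes <- length(genes)
  idx_sets <- lapply(names(sets), function(nm) {
    idx <- which(genes %in% sets[[nm]])
    if (!length(idx))
      stop(sprintf("gene set '%s' shares no genes with the matrix", nm))
    if (length(idx) == n_genes)
      stop(sprintf("gene set '%s' equals the whole gene universe", nm))
    idx
  })
  names(idx_sets) <- names(sets)

  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(-r, seq_len(n_genes))       # walk top-down; ties by position
    w <- r[ord]^alpha
    for (si in seq_along(idx_sets)) {
      inset <- logical(n_genes)
      inset[idx_sets[[si]]] <- TRUE
      inset <- inset[ord]
      ecdf_in <- cumsum(w * inset) / sum(w[inset])
      ecdf_out <- cumsum(!inset) / (n_genes - sum(inset))
      scores[si, j] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  attr(scores, "normalized") <- normalize
  scores
}

#' Pattern-level signature characterization
#'
#' For each pattern, each gene set's enrichment scores are compared
#' one-vs-rest with a Welch t test; BH adjustment runs across sets within a
#' pattern. A (pattern, set) pair is flagged when the mean-score difference
#' exceeds `diff_threshold` and the adjusted p-value falls below `alpha`.
#'
#' @param enr sets x samples enrichment matrix (e.g. [ssgsea_scores()]).
#' @param labels a `pattern_assignment` or a named label vector covering
#'   every sample column of `enr`.
#' @param diff_threshold minimum mean-score difference (pattern minus rest).
#' @param alpha adjusted-p cutoff.
#' @return data.frame: pattern, set, diff, p, p_adj, flagged.
#' @export
characterize_patterns <- function(enr, labels, diff_threshold = 0.15,
                                  alpha = 0.05) {
  stopifnot(is.matrix(enr))
  lab <- pattern_labels(labels)
  missing <- setdiff(colnames(enr), names(lab))
  if (length(missing))
    stop("unlabeled samples: ", paste(missing, collapse = ", "))
  lab <- lab[colnames(enr)]
  out <- list()
  for (p in levels(factor(lab))) {
    in_p <- lab == p
    if (sum(in_p) < 2L || sum(!in_p) < 2L)
      stop("pattern ", p, " needs >= 2 samples on each side")
    de <- two_group_de(enr, factor(ifelse(in_p, "zz_pattern", "rest")))
    out[[p]] <- data.frame(pattern = p, set = de$gene, diff = de$logFC,
                           p = de$p, p_adj = de$p_adj,
                           flagged = de$logFC > diff_threshold &
                             de$p_adj < alpha,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("signature_table", "data.frame")
  res
}

# Accept either a pattern_assignment or a bare named vector of labels.
pattern_labels <- function(labels) {
  if (inherits(labels, "pattern_assignment")) return(labels$labels)
  if (is.null(names(labels))) stop("labels must be named by sample")
  labels
}
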