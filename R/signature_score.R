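# Ubiquitin-score derivation: correlate each regulator gene with the
# ordered pattern labels, run Boruta-style all-relevant selection on the
# positively and negatively correlated pools separately, and score each
# sample as PC1(signature genes A) - PC1(signature genes B).

#' Per-gene Pearson correlation with the pattern ordering
#'
#' @param expr genes x samples matrix.
#' @param labels a `pattern_assignment` or named label vector.
#' @param encoding `"ordinal"` (A=1, B=2, ...) or `"onehot:<pattern>"`
#'   (indicator of one pattern).
#' @return data.frame: gene, r, degenerate (TRUE for constant genes, which
#'   get r = 0 by convention).
#' @export
pattern_correlation <- function(expr, labels, encoding = "ordinal") {
  stopifnot(is.matrix(expr))
  lab <- pattern_labels(labels)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  lab <- lab[colnames(expr)]
  if (anyNA(lab)) stop("every sample must be labeled")
  if (length(unique(lab)) < 2L) stop("need at least 2 distinct patterns")
  if (identical(encoding, "ordinal")) {
    code <- as.numeric(factor(lab, levels = sort(unique(as.character(lab)))))
  } else if (startsWith(encoding, "onehot:")) {
    target <- sub("^onehot:", "", encoding)
    if (!target %in% as.character(lab))
      stop("pattern '", target, "' not present in labels")
    code <- as.numeric(as.character(lab) == target)
  } else stop("unknown encoding: ", encoding)

  s <- apply(expr, 1L, sd)
  degenerate <- s == 0
  r <- rep(0, nrow(expr))
  if (any(!degenerate))
    r[!degenerate] <- as.numeric(cor(t(expr[!degenerate, , drop = FALSE]), code))
  data.frame(gene = rownames(expr), r = r, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided exact binomial p-value for hit count h out of n at prob 0.5.
binom_p2 <- function(h, n) {
  if (n == 0) return(1)
  min(1, 2 * min(pbinom(h, n, 0.5), pbinom(h - 1L, n, 0.5, lower.tail = FALSE)))
}

#' Boruta-style all-relevant feature selection
#'
#' Each iteration appends a shuffled "shadow" copy of every live feature,
#' fits a random-forest classifier (compiled Gini-importance engine,
#' 500 trees) on the pattern labels, and records a hit when a real feature's
#' importance exceeds the maximum shadow importance. Accumulated hit counts
#' are tested against Binomial(iter, 1/2) two-sided with Bonferroni
#' correction over the starting feature count; significant features are
#' confirmed (hits high) or rejected (hits low), rejected features leave the
#' model. Features unresolved after `max_iter` iterations are tentative and
#' resolved by comparing their median importance to the median of the
#' per-iteration maximum shadow importance (`keep` column).
#'
#' @param expr features x samples matrix (features are genes).
#' @param response class label per sample (>= 2 classes).
#' @param max_iter maximum Boruta iterations.
#' @param alpha two-sided significance level (Bonferroni-corrected).
#' @param seed RNG seed (shuffles and forests both draw from R's RNG).
#' @param ntree trees per forest.
#' @param importance `"permutation"` (out-of-bag mean-decrease-in-accuracy
#'   Z-score, the default) or `"gini"` (in-bag mean-decrease-in-impurity).
#'   OOB permutation importance keeps irrelevant features exchangeable with
#'   their shadows; in-bag Gini gain rewards in-sample chance correlation
#'   and inflates false confirmations on null data.
#' @return data.frame: gene, hits, n_iter, median_importance, status
#'   (confirmed | rejected | tentative), keep.
#' @export
boruta_select <- function(expr, response, max_iter = 100L, alpha = 0.01,
                          seed = 1L, ntree = 500L,
                          importance = c("permutation", "gini")) {
  importance <- match.arg(importance)
  imp_fun <- if (importance == "permutation") .rf_perm_importance
             else .rf_gini_importance
  stopifnot(is.matrix(expr))
  if (nrow(expr) < 2L) stop("need at least 2 features")
  if (ncol(expr) < 10L) stop("need at least 10 samples")
  if (!is.null(names(response))) response <- response[colnames(expr)]
  y <- as.integer(factor(response)) - 1L
  if (anyNA(y)) stop("response has missing labels")
  if (length(unique(y)) < 2L) stop("response has a single class")
  set.seed(derive_seed(seed, 5L))

  x_all <- t(expr)                               # samples x features
  p0 <- ncol(x_all)
  features <- colnames(x_all)
  alpha_adj <- alpha / p0
  status <- setNames(rep("tentative", p0), features)
  hits <- setNames(integer(p0), features)
  iters <- setNames(integer(p0), features)
  imp_hist <- vector("list", p0); names(imp_hist) <- features
  shadow_max_hist <- numeric(0)
  live <- features

  for (it in seq_len(max_iter)) {
    x <- x_all[, live, drop = FALSE]
    # shadows are shuffled copies of ALL original features (not just the
    # live ones): the null pool keeps its original width, so the max-shadow
    # threshold stays calibrated to the starting feature count even after
    # rejected features leave the forest
    shadow <- apply(x_all, 2L, sample)
    imp <- imp_fun(cbind(x, shadow), y, ntree = as.integer(ntree),
                   mtry = 0L, min_node = 5L)
    real_imp <- imp[seq_along(live)]
    shadow_best <- max(imp[-seq_along(live)])
    shadow_max_hist <- c(shadow_max_hist, shadow_best)
    hit <- real_imp > shadow_best
    hits[live] <- hits[live] + hit
    iters[live] <- it
    for (i in seq_along(live))
      imp_hist[[live[i]]] <- c(imp_hist[[live[i]]], real_imp[i])

    pvals <- vapply(live, function(f) binom_p2(hits[[f]], it), 0)
    sig <- pvals < alpha_adj
    status[live[sig & hits[live] > it / 2]] <- "confirmed"
    status[live[sig & hits[live] < it / 2]] <- "rejected"
    live <- names(status)[status == "tentative"]
    if (!length(live)) break
  }

  med_imp <- vapply(features, function(f)
    if (length(imp_hist[[f]])) median(imp_hist[[f]]) else 0, 0)
  med_shadow <- median(shadow_max_hist)
  keep <- status == "confirmed" |
    (status == "tentative" & med_imp > med_shadow)
  data.frame(gene = features, hits = as.integer(hits),
             n_iter = as.integer(iters), median_importance = med_imp,
             status = unname(status), keep = unname(keep),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample PC1 signature scores and the ubiquitin score
#'
#' Genes are standardized; the first principal component of the
#' samples x genes_A matrix gives one value per sample (likewise genes_B).
#' Each PC1 is sign-oriented to correlate positively with the mean
#' expression of its own gene set, so the score does not depend on the
#' arbitrary sign of the eigenvector. The ubiquitin score is
#' `PC1_A - PC1_B`.
#'
#' @param expr genes x samples matrix containing all signature genes.
#' @param genes_a,genes_b the two signature gene lists (>= 2 usable genes
#'   each; zero-variance genes are dropped with a warning).
#' @return a `score_result`: data.frame (sample, pc1_a, pc1_b, score) with
#'   loading vectors in attributes `loadings_a` / `loadings_b`.
#' @export
pc1_score <- function(expr, genes_a, genes_b) {
  stopifnot(is.matrix(expr))
  pc_side <- function(genes, side) {
    genes <- intersect(genes, rownames(expr))
    sub <- expr[genes, , drop = FALSE]
    usable <- apply(sub, 1L, sd) > 0
    if (any(!usable))
      warning("dropping zero-variance ", side, " genes: ",
              paste(genes[!usable], collapse = ", "))
    sub <- sub[usable, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("signature side ", side, " has fewer than 2 usable genes")
    z <- standardize_rows(sub)
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = 1L)
    v <- pc$x[, 1L]
    ref <- colMeans(sub)
    if (cor(v, ref) < 0) {
      v <- -v
      pc$rotation[, 1L] <- -pc$rotation[, 1L]
    }
    list(values = v, loadings = pc$rotation[, 1L])
  }
  a <- pc_side(genes_a, "A")
  b <- pc_side(genes_b, "B")
  res <- data.frame(sample = colnames(expr), pc1_a = as.numeric(a$values),
                    pc1_b = as.numeric(b$values),
                    score = as.numeric(a$values - b$values),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "loadings_a") <- a$loadings
  attr(res, "loadings_b") <- b$loadings
  class(res) <- c("score_result", "data.frame")
  res
}

#' Derive the signature partition and ubiquitin score from labeled samples
#'
#' Runs [pattern_correlation()], splits genes into the positively and
#' negatively correlated pools (non-degenerate genes only, optional
#' `min_abs_r` floor), applies [boruta_select()] to each pool separately,
#' keeps confirmed genes plus tentative genes above the median shadow
#' importance, and computes the per-sample score with [pc1_score()].
#'
#' @param expr genes x samples matrix (typically the regulator submatrix).
#' @param labels a `pattern_assignment` or named label vector.
#' @param seed RNG seed for the two Boruta runs.
#' @param encoding passed to [pattern_correlation()].
#' @param min_abs_r optional absolute-correlation floor for pool entry.
#' @param ... further arguments for [boruta_select()].
#' @return list: `partition` (data.frame gene/pool/r/status/keep),
#'   `genes_a`, `genes_b`, `score` (a `score_result`).
#' @export
derive_signature <- function(expr, labels, seed = 1L, encoding = "ordinal",
                             min_abs_r = 0, ...) {
  pc <- pattern_correlation(expr, labels, encoding = encoding)
  lab <- pattern_labels(labels)[colnames(expr)]
  pools <- list(A = pc$gene[!pc$degenerate & pc$r > 0 & abs(pc$r) >= min_abs_r],
                B = pc$gene[!pc$degenerate & pc$r < 0 & abs(pc$r) >= min_abs_r])
  selections <- lapply(seq_along(pools), function(i) {
    genes <- pools[[i]]
    if (length(genes) < 2L)
      stop("pool ", names(pools)[i], " has fewer than 2 candidate genes")
    sel <- boruta_select(expr[genes, , drop = FALSE], lab,
                         seed = derive_seed(seed, 10L + i), ...)
    sel$pool <- names(pools)[i]
    sel
  })
  partition <- do.call(rbind, selections)
  partition$r <- pc$r[match(partition$gene, pc$gene)]
  genes_a <- partition$gene[partition$pool == "A" & partition$keep]
  genes_b <- partition$gene[partition$pool == "B" & partition$keep]
  score <- pc1_score(expr, genes_a, genes_b)
  list(partition = partition, genes_a = genes_a, genes_b = genes_b,
       score = score)
}
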