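# Resampled k-means consensus clustering with CDF / delta-area model
# selection (Monti-style). Genes are standardized, samples are repeatedly
# subsampled without replacement, k-means (k-means++ seeding, Euclidean) is
# run per draw, and the consensus matrix records how often each co-sampled
# pair lands in one cluster. Final labels come from an average-linkage cut
# of 1 - consensus, with a canonical A/B/C naming convention.

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1L, prob = prob)
    d2_new <- rowSums((x - matrix(x[centers[i + 1L], ], n, ncol(x),
                                  byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  x[centers, , drop = FALSE]
}

run_kmeans <- function(x, k, restarts = 10L, iter_max = 100L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    cent <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      kmeans(x, centers = cent, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

#' Resampled k-means consensus clustering
#'
#' For each k in `k_range` and each of `reps` draws: subsample
#' `subsample * n` samples without replacement, run k-means with k-means++
#' seeding on the standardized gene rows, and accumulate co-cluster /
#' co-sample pair counts. The consensus entry (i, j) is the proportion of
#' co-sampled draws in which i and j co-clustered; the diagonal is forced
#' to 1.
#'
#' @param expr genes x samples matrix (typically the regulator submatrix).
#' @param k_range integer vector of cluster numbers, each in \[2, n).
#' @param reps number of resampling repetitions per k.
#' @param subsample fraction of samples drawn per repetition.
#' @param seed master seed; per-k streams are derived from it.
#' @param restarts k-means restarts per draw.
#' @return a `consensus_result`: list with `consensus` (per-k matrices),
#'   `co_sampled` (pair-count matrices), `k_range`, `expr` (standardized),
#'   and the call parameters.
#' @export
consensus_cluster <- function(expr, k_range = 2:6, reps = 1000L,
                              subsample = 0.8, seed = 1L, restarts = 10L) {
  stopifnot(is.matrix(expr))
  n <- ncol(expr)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range >= n))
    stop("every k must satisfy 2 <= k < n_samples")
  if (n < 2L * max(k_range))
    stop("need at least 2 * max(k_range) samples")
  reps <- check_count(reps, "reps")
  if (subsample <= 0 || subsample > 1) stop_cfg("subsample", "must be in (0, 1]")

  z <- standardize_rows(expr)
  x <- t(z)                                   # samples x genes
  m <- max(2L, floor(subsample * n))
  consensus <- co_sampled <- vector("list", length(k_range))
  names(consensus) <- names(co_sampled) <- paste0("k", k_range)

  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    set.seed(derive_seed(seed, 100L + k))
    conn <- matrix(0, n, n)
    count <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m))
      cl <- run_kmeans(x[idx, , drop = FALSE], k, restarts = restarts)
      memb <- outer(cl, cl, "==") * 1
      conn[idx, idx] <- conn[idx, idx] + memb
      count[idx, idx] <- count[idx, idx] + 1
    }
    cons <- ifelse(count > 0, conn / pmax(count, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- dimnames(count) <- list(colnames(expr), colnames(expr))
    if (any(count[upper.tri(count)] == 0))
      warning("some sample pairs were never co-sampled at k = ", k)
    consensus[[ki]] <- cons
    co_sampled[[ki]] <- count
  }
  structure(list(consensus = consensus, co_sampled = co_sampled,
                 k_range = k_range, expr = expr, reps = reps,
                 subsample = subsample, seed = seed),
            class = "consensus_result")
}

#' Consensus CDF area and delta-area per k
#'
#' The empirical CDF of the upper-triangular consensus entries is evaluated
#' on a fixed 101-point grid over \[0, 1\] and integrated by the trapezoid
#' rule. The delta area is the raw area at the smallest k and the relative
#' increase `(area(k) - area(k-1)) / area(k-1)` for larger k.
#'
#' @param result a [consensus_cluster()] result.
#' @return data.frame: k, area, delta_area.
#' @export
cdf_delta_area <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(result$k_range) < 2L) stop("need at least two values of k")
  grid <- seq(0, 1, length.out = 101L)
  areas <- vapply(result$consensus, function(cons) {
    vals <- cons[upper.tri(cons)]
    if (length(unique(vals)) == 1L)
      warning("degenerate consensus matrix (all entries equal)")
    cdf <- vapply(grid, function(g) mean(vals <= g), 0)
    sum(diff(grid) * (head(cdf, -1) + cdf[-1]) / 2)
  }, 0)
  delta <- c(areas[1], diff(areas) / head(areas, -1))
  data.frame(k = result$k_range, area = as.numeric(areas),
             delta_area = as.numeric(delta), row.names = NULL)
}

#' Final pattern assignment at a chosen k
#'
#' Average-linkage hierarchical clustering on 1 - consensus, cut at k.
#' Labels are canonicalized: clusters are ordered by the ascending mean
#' projection of their members on the first principal component of the
#' standardized input matrix (PC1 sign fixed so its largest-magnitude gene
#' loading is positive) and named A, B, C, ... in that order.
#'
#' @param result a [consensus_cluster()] result.
#' @param k number of patterns; must be in the computed `k_range`.
#' @return a `pattern_assignment`: list with `labels` (named factor A/B/...),
#'   `k`, and `silhouette` (per-sample silhouette on 1 - consensus).
#' @export
assign_patterns <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  if (!k %in% result$k_range) stop("k = ", k, " was not computed")
  cons <- result$consensus[[paste0("k", k)]]
  d <- as.dist(1 - cons)
  cl <- cutree(hclust(d, method = "average"), k = k)
  sizes <- tabulate(cl, nbins = k)
  if (any(sizes == 0)) stop("empty cluster after cut at k = ", k)

  z <- standardize_rows(result$expr)
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = 1L)
  rot <- pc$rotation[, 1L]
  if (rot[which.max(abs(rot))] < 0) pc$x[, 1L] <- -pc$x[, 1L]
  proj <- pc$x[, 1L]
  order_means <- vapply(seq_len(k), function(i) mean(proj[cl == i]), 0)
  rank_map <- match(seq_len(k), order(order_means))
  labels <- factor(LETTERS[rank_map[cl]], levels = LETTERS[seq_len(k)])
  names(labels) <- colnames(cons)

  sil <- consensus_silhouette(1 - cons, as.integer(labels))
  structure(list(labels = labels, k = k, silhouette = sil),
            class = "pattern_assignment")
}

consensus_silhouette <- function(dmat, cl) {
  n <- length(cl)
  vapply(seq_len(n), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(dmat[i, own]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(dmat[i, cl == g]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
}
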