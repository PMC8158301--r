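#' @useDynLib ubipattern, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree hclust as.dist prcomp p.adjust pt pchisq pbinom
#'   pnorm rbinom rexp rnorm runif sd quantile median setNames mad kmeans
#'   complete.cases var wilcox.test
#' @importFrom utils head modifyList write.table read.delim
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_cfg(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (strict && x <= 0) ||
      (!strict && x < 0))
    stop_cfg(field, if (strict) "must be > 0" else "must be >= 0")
  as.numeric(x)
}

#' Standardize matrix rows to mean 0, SD 1
#'
#' Rows with zero variance are set to all zeros (they carry no signal and
#' would otherwise produce NaN).
#'
#' @param x numeric matrix.
#' @return matrix of the same shape.
#' @keywords internal
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0 | !is.finite(s)] <- Inf   # zero-variance rows -> all zeros
  (x - mu) / s
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' relabeling), expectation 0 under independent random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return a single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# Benjamini-Hochberg wrapper kept as a single choke point so every module
# adjusts p-values identically.
bh_adjust <- function(p) p.adjust(p, method = "BH")
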