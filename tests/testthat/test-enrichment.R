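make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), nrow = n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

test_that("engine agrees with the direct-summation oracle, ties included", {
  expr <- make_expr(15, 4, seed = 2)
  expr[3, 1] <- expr[7, 1]                      # force a tie
  sets <- list(A = paste0("g", c(1, 5, 9, 12)), B = paste0("g", c(2, 3, 7)))
  got <- ssgsea_scores(expr, sets, alpha = 0.25, normalize = FALSE)
  want <- ssgsea_oracle(expr, sets, alpha = 0.25)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("scores are rank-based and normalization rescales globally", {
  expr <- make_expr(30, 5, seed = 3)
  sets <- list(A = paste0("g", 1:6), B = paste0("g", 10:14))
  raw <- ssgsea_scores(expr, sets, normalize = FALSE)
  # strictly monotone transform of each sample leaves scores unchanged
  expect_equal(ssgsea_scores(exp(expr), sets, normalize = FALSE), raw)
  # two samples with the same rank order score identically
  expr2 <- expr
  expr2[, 2] <- 5 + 2 * expr[, 1]
  r2 <- ssgsea_scores(expr2, sets, normalize = FALSE)
  expect_equal(r2[, 2], r2[, 1], ignore_attr = TRUE)
  # global max-min normalization
  norm <- ssgsea_scores(expr, sets, normalize = TRUE)
  expect_equal(norm, raw / diff(range(raw)), ignore_attr = TRUE)
})

test_that("top placement maximizes ES over all 28 placements of a 2-gene set", {
  positions <- t(combn(8, 2))
  # set genes are whichever genes sit at the two chosen rank positions
  es <- apply(positions, 1, function(pos) {
    vals <- seq(8, 1)                    # distinct, rank = value order
    expr <- matrix(vals, ncol = 1,
                   dimnames = list(paste0("g", 1:8), "s1"))
    ssgsea_scores(expr, list(S = paste0("g", pos)), normalize = FALSE)[1, 1]
  })
  expect_equal(which.max(es), 1L)        # positions (1, 2) = top two ranks
})

test_that("alpha = 0 reversal negates the score and sets are independent", {
  expr <- make_expr(20, 3, seed = 4)
  sets <- list(A = paste0("g", 1:5), B = paste0("g", 11:15))
  fwd <- ssgsea_scores(expr, sets, alpha = 0, normalize = FALSE)
  rev <- ssgsea_scores(-expr, sets, alpha = 0, normalize = FALSE)
  expect_equal(rev, -fwd, ignore_attr = TRUE, tolerance = 1e-12)

  joint <- ssgsea_scores(expr, sets, normalize = FALSE)
  solo <- rbind(ssgsea_scores(expr, sets["A"], normalize = FALSE),
                ssgsea_scores(expr, sets["B"], normalize = FALSE))
  expect_equal(joint, solo, ignore_attr = TRUE)
})

test_that("degenerate sets are rejected by name", {
  expr <- make_expr(10, 2)
  expect_error(ssgsea_scores(expr, list(bad = c("zz1", "zz2"))), "bad")
  expect_error(ssgsea_scores(expr, list(all = paste0("g", 1:10))), "all")
})

test_that("characterize_patterns flags planted shifts and respects thresholds", {
  set.seed(8)
  enr <- matrix(rnorm(6 * 60, sd = 0.2), nrow = 6,
                dimnames = list(paste0("set", 1:6), paste0("s", 1:60)))
  labels <- setNames(rep(c("A", "B", "C"), each = 20), colnames(enr))
  enr["set3", labels == "B"] <- enr["set3", labels == "B"] + 1

  tab <- characterize_patterns(enr, labels)
  expect_true(tab$flagged[tab$pattern == "B" & tab$set == "set3"])
  expect_equal(sum(tab$flagged[tab$set != "set3"]), 0)
  expect_false(any(characterize_patterns(enr, labels,
                                         diff_threshold = Inf)$flagged))
  expect_error(characterize_patterns(enr, labels[-(1:19)]), "unlabeled")
})

test_that("permutation null keeps the flagged fraction near the test level", {
  set.seed(9)
  enr <- matrix(rnorm(8 * 60, sd = 0.05), nrow = 8,
                dimnames = list(paste0("set", 1:8), paste0("s", 1:60)))
  labels <- rep(c("A", "B", "C"), each = 20)
  fracs <- vapply(1:50, function(i) {
    perm <- setNames(sample(labels), colnames(enr))
    mean(characterize_patterns(enr, perm, diff_threshold = 0)$flagged)
  }, 0)
  se <- sqrt(0.05 * 0.95 / (50 * 24))
  expect_lte(mean(fracs), 0.05 + 3 * se)
})
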