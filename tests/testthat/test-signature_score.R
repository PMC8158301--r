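test_that("pattern_correlation handles exact, reversed, constant and one-hot cases", {
  labels <- setNames(rep(c("A", "B", "C"), each = 4), paste0("s", 1:12))
  code <- rep(1:3, each = 4)
  expr <- rbind(exact = code, reversed = -code, constant = rep(2, 12),
                onehotB = as.numeric(code == 2))
  colnames(expr) <- names(labels)
  pc <- pattern_correlation(expr, labels)
  expect_equal(pc$r[pc$gene == "exact"], 1)
  expect_equal(pc$r[pc$gene == "reversed"], -1)
  expect_equal(pc$r[pc$gene == "constant"], 0)
  expect_true(pc$degenerate[pc$gene == "constant"])

  oh <- pattern_correlation(expr, labels, encoding = "onehot:B")
  expect_equal(oh$r[oh$gene == "onehotB"], 1)
  expect_error(pattern_correlation(expr, setNames(rep("A", 12), names(labels))),
               "2 distinct")
})

test_that("boruta confirms constructed signal, duplicates, and rejects nulls", {
  set.seed(21)
  n <- 120
  lab <- setNames(sample(1:3, n, replace = TRUE), paste0("s", 1:n))
  signal <- as.numeric(lab) + rnorm(n, sd = 0.1)
  expr <- rbind(sig = signal, dup = signal,
                matrix(rnorm(8 * n), nrow = 8,
                       dimnames = list(paste0("noise", 1:8), NULL)))
  colnames(expr) <- names(lab)
  sel <- boruta_select(expr, lab, seed = 77L, ntree = 200L, max_iter = 50L)
  expect_identical(sel$status[sel$gene == "sig"], "confirmed")
  # all-relevant property: an exact duplicate is also confirmed
  expect_identical(sel$status[sel$gene == "dup"], "confirmed")
  expect_true(all(sel$status[grepl("noise", sel$gene)] != "confirmed"))

  # determinism under a fixed seed
  sel2 <- boruta_select(expr, lab, seed = 77L, ntree = 200L, max_iter = 50L)
  expect_identical(sel, sel2)

  expect_error(boruta_select(expr, setNames(rep(1, n), names(lab))),
               "single class")
})

test_that("pc1_score follows its algebraic contract", {
  set.seed(31)
  n <- 60
  f <- rnorm(n)                          # latent factor
  expr <- rbind(
    a1 = f + rnorm(n, sd = 0.05), a2 = f + rnorm(n, sd = 0.05),
    a3 = f + rnorm(n, sd = 0.05),
    b1 = rnorm(n), b2 = rnorm(n), b3 = rnorm(n))
  colnames(expr) <- paste0("s", 1:n)
  res <- pc1_score(expr, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(res$score, res$pc1_a - res$pc1_b)
  expect_gte(abs(cor(res$pc1_a, f)), 0.99)
  expect_gte(cor(res$pc1_a, colMeans(expr[c("a1", "a2", "a3"), ])), 0)

  swapped <- pc1_score(expr, c("b1", "b2", "b3"), c("a1", "a2", "a3"))
  expect_equal(swapped$score, -res$score)

  negated <- pc1_score(-expr, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(negated$score, -res$score, tolerance = 1e-8)

  # invariance to gene and sample order
  perm_g <- sample(rownames(expr)); perm_s <- sample(colnames(expr))
  res_p <- pc1_score(expr[perm_g, perm_s], c("a2", "a1", "a3"),
                     c("b3", "b2", "b1"))
  expect_equal(setNames(res_p$score, res_p$sample)[res$sample],
               setNames(res$score, res$sample), tolerance = 1e-10)

  expect_error(pc1_score(expr, "a1", c("b1", "b2")), "fewer than 2")
  expr2 <- rbind(expr, flat = rep(1, n))
  expect_warning(pc1_score(expr2, c("a1", "a2", "flat"), c("b1", "b2")),
                 "zero-variance")
})

test_that("derive_signature splits pools by correlation sign and is deterministic", {
  ds <- small_planted_fixture(seed = 13L)
  labels <- setNames(LETTERS[ds$true_labels], names(ds$true_labels))
  regs <- names(ds$gene_roles)[ds$gene_roles %in%
    c("positive-regulator", "negative-regulator")]
  expr <- ds$expression[regs, ]
  sig <- derive_signature(expr, labels, seed = 3L, ntree = 150L,
                          max_iter = 30L)
  # true labels are ordered with the planted score, so pools line up with roles
  expect_true(all(ds$gene_roles[sig$genes_a] == "positive-regulator"))
  expect_true(all(ds$gene_roles[sig$genes_b] == "negative-regulator"))
  score <- setNames(sig$score$score, sig$score$sample)
  expect_gte(cor(score, ds$planted_score[names(score)]), 0.8)

  sig2 <- derive_signature(expr, labels, seed = 3L, ntree = 150L,
                           max_iter = 30L)
  expect_identical(sig$partition, sig2$partition)
  expect_identical(sig$score, sig2$score)
})
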