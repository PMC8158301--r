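test_that("fixed seed gives identical datasets and bad configs name the field", {
  cfg <- synthetic_config(n_samples = 60L, seed = 42L)
  d1 <- synthetic_dataset(cfg)
  d2 <- synthetic_dataset(cfg)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$true_labels, d2$true_labels)
  expect_identical(d1$clinical, d2$clinical)
  expect_identical(d1$gene_sets, d2$gene_sets)

  expect_error(synthetic_config(pattern_props = c(0.5, 0.4, 0.2)),
               "pattern_props")
  expect_error(synthetic_config(n_regulator_genes = 0), "n_regulator_genes")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("planted structure matches its definition", {
  ds <- generate_expression(synthetic_config(n_samples = 150L, seed = 3L))
  roles <- ds$gene_roles
  pos <- names(roles)[roles == "positive-regulator"]
  neg <- names(roles)[roles == "negative-regulator"]
  raw <- colMeans(ds$expression[pos, ]) - colMeans(ds$expression[neg, ])
  expect_equal(unname(as.numeric(scale(raw))), unname(ds$planted_score))
  expect_equal(mean(ds$planted_score), 0, tolerance = 1e-12)
  expect_equal(sd(ds$planted_score), 1, tolerance = 1e-12)

  # role map covers every gene exactly once; labels cover every sample
  expect_setequal(names(roles), rownames(ds$expression))
  expect_setequal(names(ds$true_labels), colnames(ds$expression))

  # empirical per-pattern regulator means track the configured separation
  sep <- ds$config$pattern_separation
  for (p in 2:3) {
    sel_p <- ds$true_labels == p
    sel_1 <- ds$true_labels == 1
    shift <- mean(ds$expression[pos, sel_p]) - mean(ds$expression[pos, sel_1])
    n_eff <- length(pos) * min(sum(sel_p), sum(sel_1))
    expect_lt(abs(shift - sep * (p - 1)), 3 / sqrt(n_eff) * 2)
  }
})

test_that("per-gene ANOVA oracle recovers >= 95% of regulators at separation 3", {
  ds <- generate_expression(synthetic_config(
    n_samples = 200L, n_regulator_genes = 100L, pattern_separation = 3,
    seed = 5L))
  p <- anova_p_per_gene(ds$expression, ds$true_labels)
  padj <- p.adjust(p, method = "BH")
  regs <- ds$gene_roles %in% c("positive-regulator", "negative-regulator")
  expect_gte(mean(padj[regs] < 0.05), 0.95)
})

test_that("zero separation leaves consensus clustering near chance ARI", {
  # scaled down (n = 80, 10 reps, 3 restarts) to keep the suite fast;
  # ARI is label-permutation invariant so the reduced run is still a
  # pure-noise recovery check
  aris <- vapply(1:8, function(s) {
    ds <- generate_expression(synthetic_config(
      n_samples = 80L, n_regulator_genes = 40L, n_noise_genes = 40L,
      pattern_separation = 0,
      immune_sets = list(), seed = s))
    # at 10 reps a few pairs are never co-sampled; that flag is expected here
    cr <- suppressWarnings(
      consensus_cluster(ds$expression, k_range = 3L:4L, reps = 10L,
                        seed = s, restarts = 3L))
    pa <- assign_patterns(cr, 3L)
    adjusted_rand_index(as.integer(pa$labels), ds$true_labels)
  }, 0)
  expect_lt(mean(abs(aris)), 0.1)
})

test_that("survival generation honors the planted hazard model", {
  cfg <- synthetic_config(n_samples = 2000L, survival_baseline_hazard = 0.01,
                          censor_rate = 0.01, score_log_hr = 0, seed = 9L)
  ds <- generate_expression(cfg)
  clin <- generate_survival(ds, cfg)
  # two competing exponentials at equal rates: P(censored) = 1/2
  expect_lt(abs(mean(clin$event == 0) - 0.5), 0.03)
  expect_true(all(clin$time_months > 0))

  cfg0 <- synthetic_config(n_samples = 100L, censor_rate = 0, seed = 9L)
  ds0 <- generate_expression(cfg0)
  expect_true(all(generate_survival(ds0, cfg0)$event == 1))
})

test_that("null score coefficient is covered by +/- 2 SE in >= 90% of seeds", {
  hits <- vapply(1:100, function(s) {
    cfg <- synthetic_config(n_samples = 200L, score_log_hr = 0, seed = s)
    ds <- generate_expression(cfg)
    clin <- generate_survival(ds, cfg)
    x <- matrix(ds$planted_score, ncol = 1,
                dimnames = list(names(ds$planted_score), "score"))
    fit <- cox_fit(x, clin)
    abs(fit$coefficients$coef) < 2 * fit$coefficients$se
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("gene sets mirror the planted roles and survive a GMT round trip", {
  ds <- synthetic_dataset(synthetic_config(n_samples = 40L, seed = 2L))
  sets <- ds$gene_sets
  for (s in ds$config$immune_sets)
    expect_length(sets[[s$name]], s$size)
  noise <- names(ds$gene_roles)[ds$gene_roles == "noise"]
  expect_length(intersect(unlist(sets), noise), 0)

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(sets))
  for (nm in names(sets)) expect_identical(back[[nm]], sets[[nm]])
})
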