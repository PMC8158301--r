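toy_clinical <- function(time, event, prefix = "s") {
  data.frame(sample = paste0(prefix, seq_along(time)), time_months = time,
             event = event, stringsAsFactors = FALSE)
}

test_that("log-rank matches the hand-computed toy and survdiff", {
  clin <- toy_clinical(c(1, 2, 3, 4), rep(1L, 4))
  g <- setNames(c("g1", "g1", "g2", "g2"), clin$sample)
  lr <- km_logrank(g, clin)
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-10)  # frozen hand value
  expect_equal(lr$df, 1L)

  # identical duplicated groups: no signal at all
  clin2 <- toy_clinical(rep(c(2, 5, 7, 9), 2), rep(c(1L, 0L, 1L, 1L), 2))
  g2 <- setNames(rep(c("a", "b"), each = 4), clin2$sample)
  lr2 <- km_logrank(g2, clin2)
  expect_equal(lr2$chisq, 0)
  expect_equal(lr2$p, 1)

  # three groups with ties against the survival-package oracle
  set.seed(6)
  n <- 90
  clin3 <- toy_clinical(round(rexp(n, 0.1), 1) + 0.1, rbinom(n, 1, 0.7))
  g3 <- setNames(sample(c("x", "y", "z"), n, replace = TRUE), clin3$sample)
  lr3 <- km_logrank(g3, clin3)
  sd3 <- survival::survdiff(
    survival::Surv(clin3$time_months, clin3$event) ~ g3)
  expect_equal(lr3$chisq, sd3$chisq, tolerance = 1e-8)
  # row order of the clinical table is irrelevant
  perm <- sample(n)
  lr3b <- km_logrank(g3, clin3[perm, ])
  expect_equal(lr3b$chisq, lr3$chisq, tolerance = 1e-12)
})

test_that("log-rank power at hazard ratio 3 reaches p < 0.001", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    time <- c(rexp(200, 0.03), rexp(200, 0.09))
    clin <- toy_clinical(time, rep(1L, 400))
    g <- setNames(rep(c("lo", "hi"), each = 200), clin$sample)
    km_logrank(g, clin)$p < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("KM curves are proper and the median uses the step convention", {
  set.seed(7)
  cv <- km_curve(rexp(80, 0.05), rbinom(80, 1, 0.8))
  expect_true(all(diff(cv$surv) <= 1e-12))
  expect_true(all(cv$surv <= 1))
  sf <- survival::survfit(survival::Surv(rep(c(2, 4, 6, 8), 2),
                                         rep(1, 8)) ~ 1)
  cv2 <- km_curve(rep(c(2, 4, 6, 8), 2), rep(1L, 8))
  expect_equal(cv2$surv, summary(sf)$surv, tolerance = 1e-12)
  expect_equal(km_median(cv2), 4)       # S(4) = 0.5 exactly -> step time
})

test_that("cox_fit reproduces coxph (Breslow) and honors its contract", {
  set.seed(42)
  n <- 150
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  time <- round(rexp(n, 0.05 * exp(0.5 * x[, 1] - 0.3 * x[, 2])), 1) + 0.1
  event <- rbinom(n, 1, 0.8)
  clin <- toy_clinical(time, event)
  rownames(x) <- clin$sample

  fit <- cox_fit(x, clin)
  oracle <- survival::coxph(survival::Surv(time, event) ~ a + b,
                            data = data.frame(x), ties = "breslow")
  expect_equal(fit$coefficients$coef, unname(coef(oracle)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-7)
  expect_lt(fit$gradient_norm, 1e-8)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  expect_true(all(fit$coefficients$hr_lower < fit$coefficients$hr_upper))

  # true HR 2.0 with a binary covariate: CI covers on a fixed seed
  set.seed(11)
  z <- rbinom(500, 1, 0.5)
  t2 <- rexp(500, 0.05 * exp(log(2) * z))
  clin2 <- toy_clinical(t2, rep(1L, 500))
  x2 <- matrix(z, ncol = 1, dimnames = list(clin2$sample, "z"))
  fit2 <- cox_fit(x2, clin2)
  expect_gt(fit2$coefficients$hr_upper, 2)
  expect_lt(fit2$coefficients$hr_lower, 2)

  x3 <- cbind(x, zero = 0)
  expect_warning(fit3 <- cox_fit(x3, clin), "constant")
  expect_identical(fit3$coefficients$term, c("a", "b"))
  clin_few <- clin
  clin_few$event <- c(1L, rep(0L, n - 1))
  expect_error(cox_fit(x, clin_few), "fewer events")
})

test_that("best_cutpoint respects min_prop, flags bias, and breaks ties low", {
  set.seed(12)
  n <- 300
  score <- setNames(rnorm(n), paste0("s", 1:n))
  hr <- ifelse(score > 0, 3, 1)
  clin <- toy_clinical(rexp(n, 0.02 * hr), rep(1L, n))
  cut <- best_cutpoint(score, clin, min_prop = 0.2)
  expect_true(cut$selection_biased)
  expect_gte(sum(cut$labels == "high"), ceiling(0.2 * n))
  expect_gte(sum(cut$labels == "low"), ceiling(0.2 * n))
  expect_lt(abs(cut$cutoff), quantile(abs(score), 0.35))

  expect_error(best_cutpoint(score, transform(clin, event = 0)), ">= 20")
  expect_error(best_cutpoint(score, clin, min_prop = 0.51), "min_prop")

  # all candidate p-values equal -> the lowest cutoff wins
  tied <- setNames(c(1, 2, 3, 4), paste0("t", 1:4))
  clin_t <- toy_clinical(c(5, 6, 7, 8) + 0, rep(1L, 4), prefix = "t")
  clin_t$event <- rep(1L, 4)
  clin_t$time_months <- c(3, 3, 3, 3)   # no ordering information at all
  clin_t <- rbind(clin_t,
                  toy_clinical(rep(3, 21), rep(1L, 21), prefix = "u"))
  tied <- c(tied, setNames(rep(2.5, 21), paste0("u", 1:21)))
  cut_t <- best_cutpoint(tied, clin_t, min_prop = 0.05)
  expect_equal(cut_t$p, 1)
  expect_equal(cut_t$cutoff, min(cut_t$candidates$cutoff))
})
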