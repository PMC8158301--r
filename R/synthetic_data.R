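# Synthetic cohort generator: plants K expression patterns, regulator genes
# loaded positively/negatively on the pattern ordering, immune-cell signature
# genes with pattern-dependent set-level shifts, pure-noise genes, and
# survival times whose hazard is log-linear in a planted per-sample score.

# Deterministic sub-seed derivation (Lehmer step) so independent stages draw
# from independent, reproducible streams while staying in 32-bit range.
derive_seed <- function(seed, tag) {
  step <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((step + as.numeric(tag)) %% 2147483647)
}

default_immune_sets <- function(n_patterns) {
  # Small stand-in for a curated immune-cell signature collection: two
  # "adaptive" and two "innate" cell types whose set-level abundance differs
  # across patterns (shift in units of noise SD, one entry per pattern).
  base <- list(
    list(name = "adaptive.Tcell.activated", size = 12L),
    list(name = "adaptive.Tcell.regulatory", size = 12L),
    list(name = "innate.NK", size = 12L),
    list(name = "innate.macrophage", size = 12L)
  )
  shifts <- list(c(0, 0.5, 1.5), c(0, 1.5, 0.5), c(1, 0, 1), c(0.5, 1, 0))
  for (i in seq_along(base)) {
    s <- rep_len(shifts[[i]], n_patterns)
    base[[i]]$shift <- s
  }
  base
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a three-pattern cohort: pattern proportions follow the
#' 123/246/161 split of a 530-sample ccRCC cohort, regulator genes move by
#' `pattern_separation` noise-SDs per pattern step, and survival hazard is
#' log-linear in the planted score with a hazard ratio of 1.47 per score SD.
#'
#' @param n_samples number of tumor samples.
#' @param n_patterns number of planted expression patterns.
#' @param pattern_props per-pattern sample proportions; must sum to 1.
#' @param n_regulator_genes number of pattern-loaded regulator genes (split
#'   evenly between positively and negatively loaded).
#' @param n_noise_genes number of i.i.d. noise genes.
#' @param pattern_separation mean shift per pattern step, in noise-SD units.
#' @param immune_sets list of immune signature sets; each element is a list
#'   with `name`, `size`, and `shift` (numeric, one mean shift per pattern).
#' @param noise_sd SD of the Gaussian log2-expression noise.
#' @param survival_baseline_hazard baseline event rate per month.
#' @param score_log_hr log hazard ratio per SD of the planted score.
#' @param censor_rate independent censoring rate per month (0 = no censoring).
#' @param seed integer master seed; fixed seed gives byte-identical output.
#' @return a `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_samples = 200L,
                             n_patterns = 3L,
                             pattern_props = c(123, 246, 161) / 530,
                             n_regulator_genes = 100L,
                             n_noise_genes = 152L,
                             pattern_separation = 3,
                             immune_sets = default_immune_sets(n_patterns),
                             noise_sd = 1,
                             survival_baseline_hazard = 0.01,
                             score_log_hr = log(1.47),
                             censor_rate = 0.01,
                             seed = 1L) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_patterns = check_count(n_patterns, "n_patterns"),
    pattern_props = as.numeric(pattern_props),
    n_regulator_genes = check_count(n_regulator_genes, "n_regulator_genes"),
    n_noise_genes = check_count(n_noise_genes, "n_noise_genes"),
    pattern_separation = check_pos(pattern_separation, "pattern_separation",
                                   strict = FALSE),
    immune_sets = immune_sets,
    noise_sd = check_pos(noise_sd, "noise_sd"),
    survival_baseline_hazard = check_pos(survival_baseline_hazard,
                                         "survival_baseline_hazard"),
    score_log_hr = as.numeric(score_log_hr),
    censor_rate = check_pos(censor_rate, "censor_rate", strict = FALSE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$pattern_props) != cfg$n_patterns)
    stop_cfg("pattern_props", "must have one entry per pattern")
  if (any(cfg$pattern_props <= 0))
    stop_cfg("pattern_props", "must be strictly positive")
  if (abs(sum(cfg$pattern_props) - 1) > 1e-12)
    stop_cfg("pattern_props", "must sum to 1 within 1e-12")
  for (s in cfg$immune_sets) {
    if (is.null(s$name) || is.null(s$size) || is.null(s$shift))
      stop_cfg("immune_sets", "entries need name, size and shift")
    if (length(s$shift) != cfg$n_patterns)
      stop_cfg("immune_sets", "shift must have one entry per pattern")
    check_count(s$size, "immune_sets$size")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic expression cohort with planted patterns
#'
#' Draws log2-scale expression for regulator, immune-signature and noise
#' genes. Positively loaded regulators gain `pattern_separation` noise-SDs of
#' mean per pattern step; negatively loaded regulators lose the same amount;
#' immune-set genes are shifted per their configured per-pattern shift; noise
#' genes are i.i.d. The planted per-sample score is the mean of positive
#' regulators minus the mean of negative regulators, standardized to mean 0
#' and SD 1.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list with `expression` (genes x samples),
#'   `true_labels` (named integer pattern per sample), `gene_roles` (named
#'   character), `planted_score` (named numeric), `config`, and `clinical`
#'   (NULL until [generate_survival()] runs).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_samples
  K <- config$n_patterns
  sep <- config$pattern_separation * config$noise_sd

  # deterministic label assignment honoring the configured proportions
  counts <- floor(config$pattern_props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- config$pattern_props * n - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  labels <- sample(rep.int(seq_len(K), counts))
  samples <- sprintf("S%04d", seq_len(n))
  names(labels) <- samples

  n_pos <- ceiling(config$n_regulator_genes / 2)
  n_neg <- config$n_regulator_genes - n_pos
  n_imm <- vapply(config$immune_sets, function(s) as.integer(s$size), 1L)
  genes <- c(sprintf("REGP%03d", seq_len(n_pos)),
             if (n_neg > 0) sprintf("REGN%03d", seq_len(n_neg)),
             unlist(lapply(seq_along(config$immune_sets), function(i)
               sprintf("IMM%d_%03d", i, seq_len(n_imm[i])))),
             sprintf("NOISE%04d", seq_len(config$n_noise_genes)))
  roles <- c(rep("positive-regulator", n_pos),
             rep("negative-regulator", n_neg),
             unlist(lapply(config$immune_sets, function(s)
               rep(paste0("immune:", s$name), s$size))),
             rep("noise", config$n_noise_genes))
  names(roles) <- genes
  G <- length(genes)

  base_mean <- rnorm(G, mean = 8, sd = 1.5)           # per-gene log2 baseline
  mu <- matrix(base_mean, nrow = G, ncol = n)
  step <- labels - 1L                                  # 0-based pattern index
  pos_idx <- which(roles == "positive-regulator")
  neg_idx <- which(roles == "negative-regulator")
  mu[pos_idx, ] <- mu[pos_idx, ] + rep(sep * step, each = length(pos_idx))
  mu[neg_idx, ] <- mu[neg_idx, ] - rep(sep * step, each = length(neg_idx))
  offset <- length(pos_idx) + length(neg_idx)
  for (i in seq_along(config$immune_sets)) {
    rows <- offset + seq_len(n_imm[i])
    shift <- config$immune_sets[[i]]$shift[labels] * config$noise_sd
    mu[rows, ] <- mu[rows, ] + rep(shift, each = length(rows))
    offset <- offset + n_imm[i]
  }
  expr <- mu + matrix(rnorm(G * n, sd = config$noise_sd), nrow = G)
  dimnames(expr) <- list(genes, samples)

  raw <- colMeans(expr[pos_idx, , drop = FALSE]) -
    colMeans(expr[neg_idx, , drop = FALSE])
  planted <- as.numeric(scale(raw))
  names(planted) <- samples

  structure(list(expression = expr, true_labels = labels, gene_roles = roles,
                 planted_score = planted, clinical = NULL, config = config),
            class = "synthetic_dataset")
}

#' Generate score-linked survival for a synthetic cohort
#'
#' Event times are exponential with hazard
#' `survival_baseline_hazard * exp(score_log_hr * planted_score)`; censoring
#' is an independent exponential clock at `censor_rate`. The observed time is
#' the earlier of the two, with the event flag set accordingly. Independent
#' age / gender / stage / grade covariates are attached for multivariate
#' survival modeling.
#'
#' @param dataset a `synthetic_dataset` with `planted_score`.
#' @param config the same [synthetic_config()] used to build `dataset`.
#' @return a `data.frame` clinical table: sample, time_months, event, age,
#'   gender, stage, grade.
#' @export
generate_survival <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (is.null(dataset$planted_score)) stop("dataset lacks planted_score")
  set.seed(derive_seed(config$seed, 2L))
  score <- dataset$planted_score
  n <- length(score)
  hazard <- config$survival_baseline_hazard * exp(config$score_log_hr * score)
  t_event <- rexp(n, rate = hazard)
  t_cens <- if (config$censor_rate > 0) rexp(n, rate = config$censor_rate)
            else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  data.frame(
    sample = names(score),
    time_months = time,
    event = event,
    age = round(rnorm(n, 60, 10)),
    gender = sample(c(0L, 1L), n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15)),
    grade = sample(1:4, n, replace = TRUE, prob = c(0.15, 0.4, 0.3, 0.15)),
    stringsAsFactors = FALSE
  )
}

#' Emit the gene-set collection implied by the planted gene roles
#'
#' One set per configured immune signature (exactly its role-tagged genes)
#' plus a `regulators` set holding every planted regulator gene.
#'
#' @param dataset a `synthetic_dataset` with `gene_roles`.
#' @return named list of character vectors with a `provenance` attribute.
#' @export
generate_gene_sets <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  roles <- dataset$gene_roles
  if (is.null(roles) || !length(roles)) stop("dataset lacks gene_roles")
  set_names <- vapply(dataset$config$immune_sets, `[[`, "", "name")
  sets <- lapply(set_names, function(nm) {
    members <- names(roles)[roles == paste0("immune:", nm)]
    if (!length(members))
      stop(sprintf("immune set '%s' has no role-tagged genes", nm))
    members
  })
  names(sets) <- set_names
  sets$regulators <- names(roles)[roles %in%
    c("positive-regulator", "negative-regulator")]
  attr(sets, "provenance") <- "synthetic"
  sets
}

#' Generate a complete synthetic dataset (expression + survival + gene sets)
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` with `clinical` and `gene_sets` filled in.
#' @export
synthetic_dataset <- function(config = synthetic_config()) {
  ds <- generate_expression(config)
  ds$clinical <- generate_survival(ds, config)
  ds$gene_sets <- generate_gene_sets(ds)
  ds
}
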