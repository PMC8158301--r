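# End-to-end orchestration: synthetic generation (or file inputs), MAD
# filtering, optional two-cohort DE, consensus clustering, enrichment,
# signature scoring, survival stratification, and optional drug-response
# prediction. Every stage writes TSV outputs into the run directory and the
# run closes with a JSON manifest (parameters, seeds, per-stage dimensions,
# file checksums). Stage failures abort with the stage name.

default_pipeline_config <- function() {
  list(
    seed = 7L,
    synthetic = list(),               # defaults of synthetic_config()
    mad = list(threshold = 0.5),
    cluster = list(kmin = 2L, kmax = 6L, reps = 100L, subsample = 0.8,
                   restarts = 10L, k = NULL),
    enrich = list(alpha = 0.25, normalize = TRUE,
                  diff_threshold = 0.15, sig_alpha = 0.05),
    score = list(encoding = "ordinal", min_abs_r = 0, ntree = 500L,
                 max_iter = 100L),
    survival = list(min_prop = 0.1,
                    adjust = c("age", "gender", "stage", "grade")),
    drug = list(enabled = FALSE, n_cell_lines = 60L, n_genes = 30L,
                folds = 10L)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  cfg <- modifyList(default_pipeline_config(), config)
  if (is.null(cfg$seed)) stop("config must set a master seed")
  cfg
}

stage_msg <- function(stage, ...) {
  message(sprintf("[ubipattern] %s: %s", stage, paste0(...)))
}

run_stage <- function(stage, fn) {
  tryCatch(fn(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full ubiquitin-pattern pipeline
#'
#' Executes, in order: input loading (or synthetic generation), MAD noise
#' filtering, resampled k-means consensus clustering with delta-area model
#' selection, ssGSEA enrichment plus pattern characterization, signature
#' derivation and ubiquitin scoring, best-separation survival
#' stratification with multivariate Cox adjustment, and (optionally)
#' ridge IC50 prediction on synthetic cell lines. All stage outputs are
#' written as TSV under `outdir`, plus `manifest.json`.
#'
#' @param config a config list or path to a YAML file; see
#'   `default_pipeline_config()` for the recognized keys. When
#'   `config$inputs` (paths `expression`, `clinical`, optional `gmt`) is
#'   absent, a synthetic cohort is generated from `config$synthetic`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), outdir) {
  cfg <- read_pipeline_config(config)
  if (missing(outdir)) stop("outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ubipattern",
                   version = as.character(utils::packageVersion("ubipattern")),
                   seed = cfg$seed, parameters = cfg, stages = list())
  res <- list()

  if (is.null(cfg$inputs)) {
    run_stage("simulate", function() {
      sc <- do.call(synthetic_config,
                    c(cfg$synthetic, list(seed = cfg$seed)))
      ds <- synthetic_dataset(sc)
      res$dataset <<- ds
      res$expr <<- ds$expression
      res$clinical <<- ds$clinical
      res$sets <<- ds$gene_sets
      write_expression(ds$expression, file.path(outdir, "expression.tsv"))
      write_clinical(ds$clinical, file.path(outdir, "clinical.tsv"))
      write_gmt(ds$gene_sets, file.path(outdir, "gene_sets.gmt"))
      write.table(data.frame(sample = names(ds$true_labels),
                             pattern = ds$true_labels,
                             planted_score = ds$planted_score),
                  file.path(outdir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$stages$simulate <<- list(n_genes = nrow(ds$expression),
                                        n_samples = ncol(ds$expression))
      stage_msg("simulate", nrow(ds$expression), " genes x ",
                ncol(ds$expression), " samples")
    })
  } else {
    run_stage("load", function() {
      res$expr <<- read_expression(cfg$inputs$expression)
      res$clinical <<- read_clinical(cfg$inputs$clinical)
      if (!is.null(cfg$inputs$gmt)) res$sets <<- read_gmt(cfg$inputs$gmt)
      manifest$stages$load <<- list(n_genes = nrow(res$expr),
                                    n_samples = ncol(res$expr))
    })
  }

  run_stage("join", function() {
    missing <- setdiff(colnames(res$expr), res$clinical$sample)
    if (length(missing))
      stop("clinical table missing sample ids: ",
           paste(missing, collapse = ", "))
    res$clinical <<- res$clinical[match(colnames(res$expr),
                                        res$clinical$sample), ]
  })

  run_stage("mad_filter", function() {
    res$filtered <<- mad_filter(res$expr, threshold = cfg$mad$threshold)
    manifest$stages$mad_filter <<- list(n_genes = nrow(res$filtered))
    stage_msg("mad_filter", nrow(res$filtered), " of ", nrow(res$expr),
              " genes retained")
  })

  run_stage("cluster", function() {
    cr <- consensus_cluster(res$filtered,
                            k_range = cfg$cluster$kmin:cfg$cluster$kmax,
                            reps = cfg$cluster$reps,
                            subsample = cfg$cluster$subsample,
                            seed = cfg$seed,
                            restarts = cfg$cluster$restarts)
    stats <- cdf_delta_area(cr)
    k <- cfg$cluster$k %||%
      stats$k[-1][which.max(stats$delta_area[-1])]  # skip raw-area k_min row
    pa <- assign_patterns(cr, k)
    res$consensus <<- cr; res$cdf_stats <<- stats; res$patterns <<- pa
    write.table(stats, file.path(outdir, "consensus_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = names(pa$labels), pattern = pa$labels,
                           silhouette = pa$silhouette),
                file.path(outdir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$cluster <<- list(chosen_k = k,
                                     sizes = as.list(table(pa$labels)))
    stage_msg("cluster", "chose k = ", k, " (",
              paste(sprintf("%s=%d", levels(pa$labels),
                            tabulate(pa$labels)), collapse = ", "), ")")
  })

  if (!is.null(res$sets)) {
    run_stage("enrich", function() {
      sets <- res$sets[setdiff(names(res$sets), "regulators")]
      if (!length(sets)) return(invisible())
      enr <- ssgsea_scores(res$expr, sets, alpha = cfg$enrich$alpha,
                           normalize = cfg$enrich$normalize)
      sig <- characterize_patterns(enr, res$patterns,
                                   diff_threshold = cfg$enrich$diff_threshold,
                                   alpha = cfg$enrich$sig_alpha)
      res$enrichment <<- enr; res$signatures <<- sig
      write_expression(enr, file.path(outdir, "enrichment.tsv"))
      write.table(sig, file.path(outdir, "pattern_signatures.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$enrich <<- list(n_sets = nrow(enr),
                                      n_flagged = sum(sig$flagged))
      stage_msg("enrich", nrow(enr), " sets scored, ", sum(sig$flagged),
                " (pattern, set) pairs flagged")
    })
  }

  run_stage("score", function() {
    sig <- derive_signature(res$filtered, res$patterns, seed = cfg$seed,
                            encoding = cfg$score$encoding,
                            min_abs_r = cfg$score$min_abs_r,
                            ntree = cfg$score$ntree,
                            max_iter = cfg$score$max_iter)
    res$signature <<- sig
    score <- setNames(sig$score$score, sig$score$sample)
    res$score <<- score
    write.table(sig$partition, file.path(outdir, "signature_partition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sig$score, file.path(outdir, "ubiquitin_score.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$score <<- list(n_genes_a = length(sig$genes_a),
                                   n_genes_b = length(sig$genes_b))
    stage_msg("score", length(sig$genes_a), " signature genes A, ",
              length(sig$genes_b), " signature genes B")
  })

  run_stage("survival", function() {
    cut <- best_cutpoint(res$score, res$clinical,
                         min_prop = cfg$survival$min_prop)
    lr <- km_logrank(cut$labels, res$clinical)
    adjust <- intersect(cfg$survival$adjust, names(res$clinical))
    fit <- cox_fit(matrix(res$score, ncol = 1L,
                          dimnames = list(names(res$score), "ubiquitin_score")),
                   res$clinical, adjust = adjust)
    res$cutpoint <<- cut; res$logrank <<- lr; res$cox <<- fit
    write.table(data.frame(sample = names(cut$labels),
                           score_group = cut$labels),
                file.path(outdir, "score_groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(fit$coefficients, file.path(outdir, "cox_fit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$survival <<- list(
      cutoff = cut$cutoff, logrank_p = lr$p,
      score_hr = fit$coefficients$hr[fit$coefficients$term == "ubiquitin_score"])
    stage_msg("survival", sprintf(
      "cutoff %.3f, log-rank p = %.3g, adjusted score HR = %.3f",
      cut$cutoff, lr$p,
      fit$coefficients$hr[fit$coefficients$term == "ubiquitin_score"]))
  })

  if (isTRUE(cfg$drug$enabled)) {
    run_stage("drug", function() {
      set.seed(derive_seed(cfg$seed, 4L))
      genes <- head(rownames(res$filtered), cfg$drug$n_genes)
      ncl <- cfg$drug$n_cell_lines
      cell <- matrix(rnorm(length(genes) * ncl, 8, 2),
                     nrow = length(genes),
                     dimnames = list(genes, sprintf("CL%03d", seq_len(ncl))))
      beta <- rnorm(length(genes), 0, 0.5)
      ic50 <- drop(crossprod(cell, beta) / length(genes)) + rnorm(ncl, 0, 0.1)
      names(ic50) <- colnames(cell)
      model <- ridge_train(cell, ic50, folds = cfg$drug$folds,
                           seed = cfg$seed)
      pred <- predict_ic50(model, res$expr)
      res$ic50 <<- pred
      write.table(data.frame(sample = names(pred), predicted_ic50 = pred),
                  file.path(outdir, "predicted_ic50.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$stages$drug <<- list(lambda = model$lambda)
      stage_msg("drug", "selected lambda = ", signif(model$lambda, 3))
    })
  }

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest$files <- as.list(setNames(
    unname(tools::md5sum(file.path(outdir, files))), files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
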