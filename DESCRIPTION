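Package: ubipattern
Title: Ubiquitin-Pattern Discovery and Ubiquitin Scoring for Tumor
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("ubipattern", "developers", email = "ubipattern@example.org",
           role = c("aut", "cre"))
Description: Discovers ubiquitin-regulator expression patterns in tumor
    cohorts and derives a per-sample ubiquitin score. Implements MAD-based
    noise filtering, a Welch-t differential-expression screen with
    two-cohort intersection, resampled k-means consensus clustering with
    CDF/delta-area model selection, single-sample gene-set enrichment
    (ssGSEA) for immune-cell and pathway signatures, Boruta-style
    all-relevant gene selection backed by a compiled random-forest
    importance engine, PCA-based signature scoring, Kaplan-Meier/log-rank
    and Cox proportional-hazards survival analysis with best-separation
    cutpoint search, and ridge-regression drug-sensitivity (IC50)
    prediction. Ships a synthetic-data generator with planted pattern
    structure and score-linked survival so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
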