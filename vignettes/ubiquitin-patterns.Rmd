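---
title: "Ubiquitin patterns and the ubiquitin score: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ubiquitin patterns and the ubiquitin score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

Clear cell renal cell carcinoma (ccRCC) cohorts can be stratified by the
expression of ubiquitin regulators — the E1/E2/E3 ligases, deubiquitinases,
and ubiquitin-binding/ubiquitin-like-domain proteins that write and erase
the ubiquitin code. `ubipattern` implements that workflow as a reusable,
fully tested pipeline:

1. **Noise filtering**: genes with unscaled median absolute deviation
   (MAD) at or below 0.5 are removed. The MAD here is the raw median of
   absolute deviations from the gene median — no 1.4826 consistency
   constant — because the cutoff is defined on that raw scale.
2. **Differential regulators**: a Welch *t* test on log-scale values with
   Benjamini–Hochberg (BH) adjustment, run per cohort; the discovery
   cohort is thresholded at adjusted *p* < 0.01 and the testing cohort at
   adjusted *p* < 0.05, and the significant sets are intersected. The
   upstream study ran DESeq2 on counts and limma on arrays; those are
   external tools tied to their data modalities, so this package
   substitutes a single, oracle-checkable test and keeps the two cohort
   thresholds as parameters. A `require_same_sign` flag optionally demands
   concordant fold-change direction (the original intersection rule does
   not state this, so it defaults to off).
3. **Consensus patterns**: resampled k-means consensus clustering.
   For each candidate k, samples are repeatedly subsampled (80% without
   replacement, the conventional item-resampling fraction for this
   procedure), k-means with k-means++ seeding is run on standardized gene
   rows under Euclidean distance (10 restarts, 100 Lloyd iterations), and
   the consensus matrix records the proportion of co-sampled draws in
   which each pair co-clustered. Model selection reads the empirical CDF
   of the consensus entries: the area under the CDF per k (trapezoid on a
   fixed 101-point grid) and the relative delta area
   `(area(k) − area(k−1)) / area(k−1)`. Final labels come from an
   average-linkage hierarchical cut of `1 − consensus` — the consensus
   matrix itself is the similarity being summarized, so cutting it is more
   faithful than a fresh k-means.
4. **Immune/pathway enrichment**: single-sample GSEA. Per sample, genes
   are ranked (ties get average ranks); walking the ranking top-down, the
   enrichment score accumulates the difference between the weighted
   in-set ECDF (weights `rank^alpha`, `alpha = 0.25`, the canonical
   exponent) and the uniform out-of-set ECDF. Scores are optionally
   normalized by the global max − min of the score matrix. The same
   engine serves the immune-cell abundance and pathway-signature analyses;
   the KDE-based GSVA variant is deliberately out of scope so that one
   engine can be exhaustively oracle-tested. Pattern-level signatures are
   flagged one-vs-rest at mean difference > 0.15 and BH-adjusted
   *p* < 0.05.
5. **Signature genes and the ubiquitin score**: each regulator gene is
   Pearson-correlated with the ordinal pattern encoding (A = 1, B = 2, …);
   positively and negatively correlated genes form two candidate pools,
   each reduced by Boruta-style all-relevant selection; the per-sample
   score is `PC1_A − PC1_B`, the difference of the first principal
   components of the two signature-gene submatrices. Each PC1 is
   sign-oriented to correlate positively with the mean expression of its
   own gene set, so the score never depends on an eigenvector's arbitrary
   sign.
6. **Survival**: Kaplan–Meier product-limit curves, the k-group log-rank
   test with full hypergeometric covariance, Cox proportional-hazards
   fits maximizing the Breslow partial likelihood by Newton–Raphson until
   the gradient norm is below 1e-8, and a best-separation cutpoint search
   that scans all admissible score midpoints for the minimal log-rank p.
7. **Drug response**: ridge regression trained on cell-line expression
   against IC50, penalty chosen by 10-fold cross-validated squared error
   over 21 log-spaced penalties in [1e-3, 1e3], then applied to tumor
   samples standardized with the training parameters.

## The synthetic world

The generator (`synthetic_config()` / `synthetic_dataset()`) emulates the
statistical structure the pipeline assumes, not any particular platform:

- **Scale**: log2-like values, Gaussian noise (`noise_sd = 1`). The
  pipeline consumes normalized expression, so no count-level simulation.
- **Patterns**: 3 latent patterns with proportions 123/246/161 of 530 —
  the pattern-size split of the motivating 530-sample cohort.
- **Regulators**: 100 genes by default, half loaded positively and half
  negatively on the pattern ordering, moving `pattern_separation = 3`
  noise-SDs per pattern step. Three SDs between adjacent patterns is a
  clearly separated regime: it makes cluster recovery a correctness test
  rather than a power study.
- **Immune signatures**: four sets (two "adaptive", two "innate", 12 genes
  each) with per-pattern mean shifts of 0–2 SD — a small stand-in for a
  curated 28-cell-type collection, which is data rather than code.
- **Planted score**: mean of positive-regulator genes minus mean of
  negative-regulator genes per sample, standardized to mean 0 / SD 1, so
  the survival effect is per score-SD.
- **Survival**: exponential event times with hazard
  `0.01/month × exp(log(1.47) × score)` — the 1.47 hazard ratio is the
  multivariate-Cox effect size reported for the score in the motivating
  study — and independent exponential censoring at 0.01/month, giving
  ~50% censoring by the competing-exponentials identity. Exponential
  clocks keep every check closed-form.

What a green test does *not* establish: robustness to batch effects,
microarray/RNA-seq platform mixtures, non-proportional hazards, count
noise, or correlated gene modules beyond the planted ones — none of which
the generator emulates.

## Numerical and algorithmic choices

- **Zero-variance genes** get r = 0 (flagged degenerate) in correlations,
  are set to all-zeros in row standardization, and are dropped with a
  warning from PCA; zero-variance-in-both-groups genes with equal means
  get p = 1 / logFC = 0 in the DE test. These conventions stop NaNs from
  propagating.
- **Ties**: average ranks in ssGSEA (walk order among tied genes follows
  matrix order, deterministically); Breslow handling for tied event times
  in Cox (the simplest consistent choice); tied minimal p-values in the
  cutpoint search resolve to the lower cutoff.
- **Canonical pattern names**: clusters are ordered by the ascending mean
  projection of their members on PC1 of the standardized clustering
  matrix and named A, B, C…; PC1's sign is fixed by making its
  largest-magnitude loading positive. This makes "pattern C" reproducible
  across runs — but the orientation is still a convention, so the
  *direction* of the ubiquitin score (which pool becomes A) can flip
  between datasets. All package guarantees are therefore stated on |r|
  and on exact A/B-swap antisymmetry; users comparing scores across
  cohorts should anchor the sign to a biological reference (e.g. the
  pattern with the worst survival).
- **Best-separation caveat**: the minimal log-rank p is an optimized
  statistic; the result always carries `selection_biased = TRUE` and no
  correction is applied (none is applied upstream either).
- **Seeds**: every stochastic stage derives its own stream from the master
  seed with a Lehmer step, so stages are independently reproducible and
  re-running any stage alone gives the run-identical answer.

## The Boruta importance backend

No random-forest package is available in the target environment, so the
package ships a compiled forest engine (Rcpp) with two importance modes:

- `"permutation"` (default): out-of-bag mean-decrease-in-accuracy
  Z-scores, the original algorithm's own convention;
- `"gini"`: in-bag mean-decrease-in-impurity, as often used for speed.

The default deviates from a Gini-importance design on measured grounds:
on a label-permuted null (50 features, n = 200) in-bag Gini gain rewards
in-sample chance correlation — the strongest chance correlate beats the
freshly shuffled shadows almost every iteration and gets falsely
confirmed in a large fraction of seeds. Out-of-bag permutation
importance evaluates features on samples the tree never saw, which keeps
irrelevant features exchangeable with their shadows; measured false
confirmations drop accordingly. (The reference implementation of the
algorithm, run on the same fixtures, shows the same in-bag pathology.)
Two further conventions: shadows are shuffled copies of **all** original
features each iteration, so the max-shadow threshold stays calibrated to
the starting feature count even after rejected features leave the forest;
and the binomial confirm/reject test is two-sided at alpha = 0.01 with
Bonferroni correction over the starting feature count. Features still
unresolved at `max_iter` stay "tentative" and are additionally resolved
(`keep` column) by comparing their median importance with the median
per-iteration max-shadow importance.

## Open questions resolved here

- *Ordinal vs one-hot pattern encoding for the gene correlations*:
  ordinal over the canonical order (the simplest reading that yields
  signed correlations and hence two pools); one-hot is available via
  `encoding = "onehot:<pattern>"`.
- *Boruta response*: the pattern label (classification), run separately
  on the positive and negative pools.
- *Tentative features*: kept when their median importance clears the
  median shadow maximum, dropped otherwise.
- *ΣPC1 reading*: the per-sample value of the first principal component
  (the sum over gene loadings), one number per sample per signature side —
  the only reading that yields a per-sample score; PC1 is fitted on the
  full cohort before any high/low split.
- *Minimum group fraction for the cutpoint search*: 0.1 per side.

## Known limitations

- The generator's immune sets shift mean expression only; real immune
  infiltration changes co-expression structure too.
- The best-separation p-value is biased low by construction; treat it as
  a ranking device, not an inference.
- Boruta decisions on borderline features are sequential-test outcomes;
  with very many iterations a strong chance correlate can still be
  confirmed on null data (an inherent property of the algorithm, shared
  by its reference implementation).
- The ridge IC50 module predicts relative sensitivity under a linear
  model on standardized expression; it does not model tissue effects or
  drug-specific nonlinearity.
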