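# ubipattern

Pattern discovery and per-sample scoring for ubiquitin-regulator
expression in tumor cohorts.

Clear cell renal cell carcinoma (ccRCC) shows coordinated dysregulation of
the ubiquitin machinery — E1/E2/E3 enzymes, deubiquitinases, and
ubiquitin-binding/ubiquitin-like-domain proteins. `ubipattern` turns the
published analysis style for this problem into a reusable pipeline:

- **MAD filter**: drop genes with unscaled median absolute deviation ≤ 0.5.
- **Differential regulators**: per-cohort Welch *t* + BH
  (adjusted *p* < 0.01 discovery, < 0.05 testing), two-cohort intersection.
- **Consensus patterns**: resampled k-means consensus clustering
  (Euclidean, k-means++ seeding, 80% sample subsampling), with model
  selection by the CDF of consensus values and its delta area, and final
  labels from an average-linkage cut of `1 − consensus`.
- **ssGSEA**: rank-based single-sample enrichment
  (`ES = Σ (weighted in-set ECDF − out-of-set ECDF)`, weights
  `rank^0.25`) for immune-cell and pathway signatures, plus one-vs-rest
  pattern characterization (mean difference > 0.15, adjusted *p* < 0.05).
- **Ubiquitin score**: genes are Pearson-correlated with the ordered
  patterns; the positive and negative pools are reduced by Boruta-style
  all-relevant selection (compiled random-forest importance engine); the
  score is `PC1_A − PC1_B` per sample.
- **Survival**: Kaplan–Meier, k-group log-rank, Cox proportional hazards
  (Breslow ties, Newton–Raphson to gradient norm < 1e-8), and
  best-separation cutpoint search.
- **Drug response**: ridge-regression IC50 models trained on cell-line
  expression with 10-fold cross-validated penalty selection.

A synthetic-data module plants known patterns, signature genes, and
score-linked exponential survival, so the whole pipeline is testable
without any external download.

## Worked example

```r
library(ubipattern)

res <- run_pipeline(
  list(seed = 7,
       cluster = list(reps = 30, kmax = 4),
       drug = list(enabled = TRUE)),
  outdir = "demo_run")
```

The run prints (messages to stderr):

```
[ubipattern] simulate: 300 genes x 200 samples
[ubipattern] mad_filter: 300 of 300 genes retained
[ubipattern] cluster: chose k = 3 (A=61, B=93, C=46)
[ubipattern] enrich: 4 sets scored, 3 (pattern, set) pairs flagged
[ubipattern] score: 67 signature genes A, 78 signature genes B
[ubipattern] survival: cutoff 0.886, log-rank p = 4.35e-05, adjusted score HR = 0.972
[ubipattern] drug: selected lambda = 15.8
```

Reading the output: the generator planted 3 patterns in a 200-sample,
300-gene cohort; the consensus delta-area criterion recovered k = 3 and
the cluster sizes (61/93/46) match the planted 123/246/161-of-530
proportions. 145 regulator/immune genes were confirmed as
pattern-associated signature genes, and the resulting per-sample score
separates survival at the best cutpoint with log-rank p ≈ 4.4e-05. The
adjusted hazard ratio of 0.972 is per raw score unit (the PC1-difference
scale spans tens of units); its direction depends on which pool the
canonical pattern ordering labels "A" — guarantees are therefore stated
on |correlation| with the planted score (≥ 0.8 on this fixture; measured
|r| = 0.9997). `demo_run/` holds every stage table (expression, patterns,
enrichment, signature partition, score, Cox fit, predicted IC50) plus a
JSON manifest with parameters and file checksums; rerunning with the
same seed reproduces every file byte-for-byte.

A command-line front end covers each stage
(`exec/ubipattern simulate|de|cluster|enrich|score|survival|drug|run`).

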