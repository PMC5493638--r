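# adipostrat

Stratifies skin-biopsy expression cohorts by **adiponectin pathway
activity**. Systemic sclerosis (SSc) skin is molecularly heterogeneous;
`adipostrat` implements the transcriptomic workflow that separates biopsies
with deregulated adiponectin signaling from normal-like ones, end to end:

* **Signature derivation** — from a two-arm (adiponectin-treated vs
  vehicle) perturbation dataset, rank genes by mean log2 difference and
  take the top *k* up- and down-regulated as a signed signature
  (`differential_response()`, `select_top_k()`, `intersect_platform()`).
* **Pathway score** — for sample *s* and signature genes *i* with signs
  *k<sub>i</sub>* ∈ {+1, −1}:

  *S<sub>s</sub>* = Σ<sub>i</sub> *k<sub>i</sub>* · (*x<sub>is</sub>* −
  mean<sub>i</sub><sup>ctr</sup>) / sd<sub>i</sub><sup>ctr</sup>,

  standardizing each gene against the healthy controls
  (`fit_control_reference()`, `compute_pathway_scores()`). Case samples at
  or below a control-derived threshold are called **low**
  (`classify_samples()`; CI-of-the-mean and mean − 1.96·SD rules).
* **Synexpression subsets** — genes Pearson-correlated with the adiponectin
  transcript (r > 0.4, p < 0.005 by default) form the anchor synexpression
  set; hierarchical clustering on it splits the cohort into **reduced** and
  **normal-like** subsets (`anchor_correlation()`,
  `select_synexpression_set()`, `cluster_samples()`, `label_clusters()`).
* **Enrichment** — disease status vs subset membership as a 2×2 table with
  cross-product odds ratio, Woolf CI and chi-square/Fisher p
  (`contingency_2x2()`, `odds_ratio()`, `association_pvalue()`). On the
  published subset counts (35/70 SSc reduced, 18/22 controls normal-like)
  this gives OR = (35·18)/(35·4) = **4.5** with chi-square p = **0.0084**.
* **Synthetic cohorts with ground truth** — seeded generators for the
  perturbation experiment and for a 22-control / 41-normal / 29-low biopsy
  cohort with planted suppression and a latent co-expression factor
  (`simulate_perturbation_dataset()`, `simulate_biopsy_cohort()`), so every
  stage is testable without any external accession.

## Worked example

```r
library(adipostrat)

report <- run_pipeline(pipeline_config(
  seed = 1,
  cohort = list(suppression_delta = 1.5, n_background_genes = 100)))
```

This simulates a perturbation experiment, derives a 20+20-gene signature,
simulates a biopsy cohort carrying it, scores and classifies every sample,
builds the synexpression set, clusters, and tabulates enrichment. With seed
1 the report prints:

```r
unlist(report$subset_counts)
#>        case_reduced    case_normal_like     control_reduced control_normal_like
#>                  32                  38                   1                  21

report$association$odds_ratio   # 17.68  — planted suppression is strongly
report$association$p_value      # 0.00044   enriched in the reduced subset

unlist(report$classification)   # control 22 | low 45 | normal 25
report$synexpression_set_size   # 49 genes recovered around the anchor
```

The reduced subset holds 32 of 70 cases but only 1 of 22 controls, and the
45 "low" calls reflect the permissive CI-of-the-mean threshold (see the
vignette for the calibrated alternative). All artifacts (expression TSV,
scores, GMT sets, heatmap matrix, ranked gene list, JSON report) are
written under `report`'s output directory.

## Documentation

The methods vignette
(`vignettes/adiponectin-pathway-stratification.Rmd`) describes the score's
identities, the two threshold readings, the generative model behind the
synthetic cohorts, and the clustering-geometry caveats; function-level
documentation is in the roxygen comments under `R/`.
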