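# tmesuite

Tumor-microenvironment (TME) subtyping of bulk tumor transcriptomes from
gene-signature scores, with the survival statistics, machine-learning
signature selection and single-cell stages that surround such an analysis in
immuno-oncology studies of colorectal and other cancers.

The core question the package addresses: given a cohort of tumors scored
against a panel of curated TME gene sets (immune, stromal and functional
signatures), how many reproducible microenvironment subtypes are there, who
belongs to which, do the subtypes differ in overall survival, which
signatures carry the prognostic signal — and do the subtypes transfer to
external cohorts measured on other platforms?

## The method in brief

* **Signature scores.** `score(sig, sample) = mean of log2 expression over
  the signature's genes` — a signatures × samples matrix `S` is the
  substrate for everything downstream.
* **Consensus NMF subtyping.** `S ≈ WH` with non-negative factors under the
  generalized Kullback–Leibler objective (multiplicative updates). For each
  candidate rank `k ∈ 3..8`, 50 random restarts are labelled by dominant
  factor and aggregated into a consensus matrix `C` (co-clustering
  frequency); the chosen `k` maximizes `cophenetic(C) × dispersion(C)`,
  where `dispersion = mean(4(C−½)²)`. The final model is the best-objective
  restart among 500.
* **Projection.** Subtype centroids (mean z-scored profiles) classify new
  cohorts by nearest-centroid Pearson correlation after cohort-wise
  standardization — invariant to per-signature affine platform shifts.
* **Survival.** Kaplan–Meier curves, K-sample log-rank with the full
  hypergeometric variance, univariate Cox per signature (Newton on the
  Breslow partial likelihood, per-SD hazard ratios), and maximally selected
  log-rank cutpoints.
* **Selection ensemble.** LASSO-Cox (10-fold CV), random-forest dual top-30
  importance ranking (Gini ∩ OOB accuracy) and SVM-RFE with a 1-SE stop;
  the three-way intersection is the consensus prognostic set.
* **Single cell.** QC (mito fraction ≤ 5%, ≥ 100 genes/cell, ≥ 5
  cells/gene), `ln(1 + 1e4·c/total)` normalization, binned-variance HVGs,
  PCA, shared-nearest-neighbour Louvain clustering, rank-sum markers
  (FDR < 0.05, |log2FC| > 0.25), hypergeometric marker-set annotation, and
  permutation-tested ligand–receptor interactions between cell groups.

Synthetic bulk and single-cell generators with planted ground truth
(`gen_bulk_cohort`, `gen_sc_cohort`) make the whole pipeline testable
offline; the methods vignette (`vignettes/tme-subtyping-methods.Rmd`)
documents every modelling choice and the generators' assumptions.

## Worked example

```r
library(tmesuite)
cohort <- gen_bulk_cohort(bulk_sim_config(seed = 1))   # 5 subtypes x 60 samples
scores <- score_signatures(cohort$expr, cohort$signatures)
fit <- tmes_fit(scores, k_range = 3:8, n_runs_survey = 50,
                n_runs_final = 200, seed = 1)
summary(fit)
```

```
Consensus NMF subtype model
TME subtype fit: k = 5, 300 samples, 20 signatures

TMES1 TMES2 TMES3 TMES4 TMES5
   60    60    60    60    60
rank chosen by cophenetic x dispersion over k = 3-8
best-run KL objective: 10.2776 (260 iterations)
consensus dispersion: 0.9727
consensus cophenetic: 0.9999
NMF rank survey (50 runs per k):
 k cophenetic dispersion product
 3     0.9949     0.4912  0.4887
 4     0.9988     0.6854  0.6846
 5     0.9996     0.9551  0.9547
 6     0.9988     0.8882  0.8871
 7     0.9971     0.8379  0.8354
 8     0.9959     0.8307  0.8273
chosen k = 5 (max cophenetic x dispersion)
```

The survey picks `k = 5`: the cophenetic coefficient is near 1 everywhere
(trees fit consensus matrices easily), but dispersion — how *binary* the
co-clustering is — peaks sharply at the planted number of subtypes, and the
product rule selects it. The recovered labels split the cohort into the five
planted groups of 60.

Subtypes differ in survival, and each signature can be screened for
prognostic direction:

```r
logrank_test(cohort$survival, fit$assignment)
#> Log-rank test: chi-square = 30.83 on 4 df, p = 3.32e-06
screen <- cox_screen(scores, cohort$survival)
head(as.data.frame(screen), 3)
#>   signature hazard_ratio    ci_low   ci_high     p_value  direction
#> 1     SIG01    0.8073256 0.6988350 0.9326589 0.003651448 protective
#> 2     SIG02    0.8882417 0.7720855 1.0218728 0.097444360    neutral
#> 3     SIG03    0.9720979 0.8462191 1.1167017 0.689192410    neutral
```

The hazard ratios are per standard deviation of the signature score; here
the generator's default subtype hazards make signatures active in low-risk
subtypes protective (HR < 1). Projection onto a second cohort is
`predict(fit, new_scores)`; the selection ensemble is
`select_signatures(scores, cohort$survival, seed = 1)`; the single-cell
stage is `gen_sc_cohort` → `qc_filter` → `sc_normalize` → `select_hvg` →
`pca_embed` → `cluster_cells` → `find_markers` → `annotate_clusters` →
`lr_permutation_test`.

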