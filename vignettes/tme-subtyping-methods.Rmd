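---
title: "Methods: consensus NMF subtyping of tumor-microenvironment signatures"
author: "tmesuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus NMF subtyping of tumor-microenvironment signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tmesuite` implements a signature-level subtyping workflow for bulk tumor
transcriptomes, together with the survival, machine-learning and single-cell
stages that typically surround it in an immuno-oncology analysis. The object
of study is not the gene-level expression matrix but a compressed
representation: each curated tumor-microenvironment (TME) gene set is scored
per sample as the arithmetic mean of its members' log2 expression, giving a
signatures x samples matrix `S`. All downstream structure — subtypes,
prognostic associations, projections — lives in this score space.

Subtypes are found by non-negative matrix factorization of `S ~ W H` with
the generalized Kullback–Leibler objective and multiplicative updates (the
Brunet variant long used for expression subtyping). Because NMF from random
initializations is stochastic, the rank `k` is chosen by consensus: for each
candidate `k`, many restarts are run, each sample is assigned to its
dominant factor, and the samples x samples consensus matrix `C` records how
often each pair co-clusters. Two summaries grade a candidate rank:

* **cophenetic coefficient** — the Pearson correlation between the distances
  `1 - C` and the cophenetic distances of their average-linkage tree; near 1
  when the consensus is tree-like, i.e. stable;
* **dispersion** — `mean(4 (C - 1/2)^2)`, which is 1 exactly when every
  entry of `C` is 0 or 1 (perfectly crisp co-clustering).

The chosen rank maximizes their product over the candidate range (ties go to
the smaller rank). The final assignment at the chosen rank is taken from the
restart with the best (lowest) KL objective, labelling each sample by its
largest max-scaled `H` coefficient, with subtypes renumbered by decreasing
size so repeated runs are comparable.

## Numerical choices

* Factors are initialized `Uniform(0,1)` scaled so `E[WH]` matches `mean(V)`;
  every restart has an explicitly derived seed, so any run is replayable.
* The KL objective is evaluated every `obj_every = 10` updates; iteration
  stops when the mean per-iteration relative change between evaluations
  falls below `tol = 1e-6` (cap `max_iter = 2000`). The multiplicative
  updates guarantee a non-increasing objective; the tests assert this on the
  dense per-iteration trace (`obj_every = 1`). The cadence only affects how
  often the objective is *measured*, not the updates themselves.
* Columns of `W` are normalized to sum 1 after convergence, compensated in
  `H`.
* Ties in the per-sample argmax go to the smallest factor index; ties in the
  rank choice go to the smallest `k`.
* A user-supplied score matrix containing negative entries (e.g. centered
  scores) has each affected row shifted up by its minimum, with a logged
  note, since the factorization requires non-negativity.
* Degenerate consensus (all off-diagonal distances equal) has no defined
  cophenetic correlation; the coefficient is `NaN` with a warning, and such
  ranks are excluded from the product maximization.

# Preprocessing of the training cohort

Three steps precede factorization, mirroring how a heterogeneous multi-study
cohort is cleaned:

1. **Outlier samples.** Samples are clustered by average linkage on
   `1 - Pearson` of their score profiles and cut in two. The smaller cluster
   is declared outlying when it holds under 2% of samples *and* merges with
   the remainder above height 0.5 (correlation below 0.5). The cut repeats
   once on the remainder. The separation guard is ours: with the size rule
   alone, a homogeneous cohort's noise-driven correlations produce arbitrary
   tiny splits and stray samples would be discarded for no reason. Samples
   with a constant profile (undefined correlation) are flagged directly.
   Both thresholds are configurable.
2. **Correlation filter.** A signature is kept when its strongest absolute
   Pearson correlation with any other signature reaches 0.3. The threshold
   was fixed once so that an independent-noise signature among correlated
   ones is reliably excluded at n >= 500 samples (its null max-|cor| then
   sits well below 0.3); lowering the threshold retains a superset.
3. **Univariate Cox screen.** Each signature is standardized (per-SD hazard
   ratios, comparable across signatures) and fit by Newton maximization of
   the Breslow partial likelihood — Breslow, rather than Efron, so that
   oracle comparisons in the tests use one stated tie convention. Direction
   calls (protective/unfavorable/neutral) use the Wald p at 0.05.
   Non-convergent or zero-variance covariates are reported neutral.

# Survival statistics

Kaplan–Meier curves use the product-limit estimator; at tied times events
precede censorings, so a subject censored at an event time is still at risk
for it. The log-rank test is the K-sample statistic with the full
hypergeometric variance matrix (`U' V^{-1} U`, df = K-1). The
maximally selected cutpoint evaluates every distinct covariate value inside
the 10–90% quantile band as a dichotomizing threshold and returns the one
maximizing the two-group log-rank statistic (ties to the lower value). Its
reported p-value is the naive log-rank p — common practice, but biased by
the selection — and the function logs a warning saying exactly that.

# Prognostic-signature selection ensemble

Three selectors run on the same cohort and their selected sets are
intersected:

* **LASSO-Cox** (`glmnet`): L1-penalized Cox over a 100-point λ path,
  event-stratified 10-fold cross-validation, λ chosen at the CV-deviance
  minimum (the most common default; the 1-SE alternative is a one-line
  change). Scores are standardized beforehand.
* **Random forest**: 1000 trees on a binary outcome; the selected set is
  the *intersection* of the top-30 rankings by Gini importance and by OOB
  permutation-accuracy importance, which naturally yields a set smaller
  than 30.
* **SVM-RFE**: linear SVM (cost 1, standardized inputs), iteratively
  removing the 10% of features with smallest squared weight; each candidate
  set along the path is scored by stratified 5-fold CV accuracy and the
  smallest set within one standard error of the best is returned.

The classifiers need a binary outcome, which overall-survival data does not
directly provide. We use vital status at a fixed horizon equal to the
cohort's median follow-up: dead by the horizon = 1, still under observation
at the horizon = 0, censored earlier = excluded. We initially considered
"any observed death vs censored-late", but under realistic (~30%) censoring
that makes cases ~80% of the cohort; CV accuracy then saturates at the
majority rate, the 1-SE rule degenerates, and RFE returns arbitrary single
features. The median-horizon status is balanced by construction and is the
standard dichotomization (e.g. 5-year survival status). Any user-supplied
binary label can be passed instead.

# Subtype projection

External cohorts are assigned by nearest centroid: training scores are
z-scored per signature, subtype centroids are mean z-profiles, and a new
cohort — z-scored per signature *within itself* — assigns each sample to
the centroid with the highest Pearson correlation over shared signatures
(at least 80% overlap required; ties to the smallest subtype index). The
cohort-wise standardization plus correlation makes the projection invariant
to any per-signature affine shift, the property needed to cross microarray
and RNA-seq platforms. Re-running the full NMF discovery per cohort is the
alternative reading of cross-cohort subtyping; both are available
(`assign_subtype` vs `tmes_fit`).

# Single-cell stage

QC filters in a fixed order so counts are reproducible: cells with
mitochondrial count fraction (genes prefixed `MT-`) above 5%, then cells
expressing fewer than 100 genes, then genes expressed in fewer than 5
cells. "Expressing over 5% of mitochondrial genes" is read as count
fraction, the standard interpretation. Normalization is
`ln(1 + 1e4 * count/total)`. Highly variable genes are ranked by variance
standardized against a 20-bin equal-occupancy median trend over mean
expression. PCA uses centered, unit-scaled genes with each component's sign
fixed so its largest-magnitude loading is positive (bit-identical reruns).
Clustering builds a k = 20 nearest-neighbour graph with Jaccard
shared-neighbour weights and runs Louvain modularity at resolution 0.8.
Markers are Wilcoxon rank-sum (normal approximation with tie correction)
per cluster vs rest, `log2FC` on `expm1`-means with a +1 pseudocount, BH
correction within cluster, retained at FDR < 0.05 and |log2FC| > 0.25.
Cluster annotation replaces manual curation with a reproducible rule: the
reference marker set with the strongest hypergeometric enrichment among the
cluster's retained positive markers (ties left unlabeled, no markers =
"unknown").

Ligand–receptor interactions between annotated groups score a (pair,
sender, receiver) triple as the mean of the ligand's sender-mean and the
receptor's receiver-mean, gate testing on 10% expressing cells in both
groups, and assess significance by permuting cluster labels (the same
permutation set reused across pairs, so a run is deterministic given its
seed). P-values use the add-one convention, `p >= 1/(1 + n_perm)`. These
are the documented defaults of the standard cell–cell communication
tooling, restated here as the normative definition. Heteromeric complexes
and spatial constraints are out of scope.

# Synthetic cohorts: what they emulate, and what they do not

The generators define the conditions under which every stage is validated.

**Bulk** (`gen_bulk_cohort`): `k_true` subtypes, each activating a distinct
round-robin subset of signatures; gene expression is baseline 5 (log2
scale) plus an `effect_size` shift on active genes plus Gaussian noise,
truncated at 0. Survival is exponential with per-sample rate
`exp(subtype_log_hazard + sum_j beta_j z_j)`, where `z_j` are standardized
true scores of designated prognostic signatures — so proportional hazards
holds exactly and Cox recovery has a known truth. Censoring is an
independent exponential with per-sample rate `lambda c/(1-c)`, giving each
sample censoring probability exactly `c` (default 0.3, a typical OS
censoring fraction). Default conditions: 5 subtypes x 60 samples, 20
signatures x 10 genes, effect 3, noise 0.5 — separation comparable to a
well-powered subtyping cohort. The selection experiments use 50 signatures
x 5 genes, effect 1, noise 1, two subtypes with zero subtype hazards and
per-SD betas of 0.8 on five signatures: subtype structure deliberately weak
so that the prognostic signal, not subtype membership, drives selection.

**Single-cell** (`gen_sc_cohort`): negative-binomial counts (mean 1, size
2) over 500 genes; 4 cell types x 100 cells with 10 disjoint marker genes
each at fold 8; 10 `MT-` genes tuned to contribute 1% of a good cell's
counts in expectation versus 30% for the 10 planted low-quality cells,
which additionally express only 60 non-mito genes (guaranteeing they fall
under the 100-gene QC threshold). The 1% good-cell level leaves ~8 SD of
margin below the 5% QC cut, so "QC removes exactly the planted cells" holds
by construction rather than by luck; 1% is within the normal range for
healthy cells. One ligand–receptor pair (fold 8, type 1 -> type 2) is
planted by default.

Neither generator models microarray probe-level noise, batch effects,
library-size gradients, doublets or ambient RNA. Passing the planted-truth
tests therefore demonstrates the *algorithmic* correctness and calibration
of each stage — not robustness to those artefacts, which the surrounding
literature handles upstream (batch correction is explicitly out of scope
here).

# Problem sizes used in validation

The shipped checks run the rank survey (ranks 3–8, 50 restarts) over 20
generator seeds at 300 samples x 20 signatures; the final assignment uses
500 restarts. Cox calibration uses one n = 2000 recovery fit and 500 null
replicates at n = 100. The selection ensemble runs its full three
algorithms on 20 seeds at n = 600 x 50 signatures. The single-cell stage
runs end to end at 410 cells x 500 genes, with 999-permutation interaction
tests and five 199-permutation null replicates. These sizes were chosen as
the smallest at which the planted effects are comfortably identifiable, so
the whole validation suite completes in minutes on a single core.

# Known limitations

* The NMF restarts can land in local KL optima; at higher ranks an
  occasional restart keeps the consensus from being perfectly binary even
  on noiseless data (the coefficients remain near 1 and the rank choice is
  unaffected). This is intrinsic to multiplicative updates from random
  starts and is why consensus, not a single run, drives rank selection.
* Cutpoint p-values are selection-biased (logged warning); use them
  descriptively.
* The Cox implementation is univariate by design (the screening use case);
  multivariable modelling, proportionality diagnostics and competing risks
  are out of scope.
* The interaction test supports single-gene ligands and receptors only.
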