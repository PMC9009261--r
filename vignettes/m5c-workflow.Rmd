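---
title: "The m5C regulator workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The m5C regulator workflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

RNA 5-methylcytosine (m5C) is deposited, removed and read by a small set of
regulator proteins — the DNMT and NSUN methyltransferase families, TRDMT1,
and the YBX1/YBX2 readers. In several tumor types the joint expression
pattern of these twelve genes separates patients into subgroups with
different immune microenvironments and different survival. `m5Cscope`
implements the complete analysis chain that turns a merged, batch-corrected
tumor expression cohort into such a stratification and ultimately into a
single per-sample prognostic quantity, the **m5C score**:

1. merge cohorts on shared genes, correct batch effects (`merge_cohorts()`,
   `combat_correct()`);
2. consensus-cluster samples on the 12 regulators into *m5C clusters*
   (`cluster_stratify()`);
3. test genes for differential expression across those clusters with a
   moderated F statistic, intersect the hits with an externally supplied
   tumor-vs-normal DEG list (`moderated_anova()`, `intersect_degs()`);
4. consensus-cluster samples again on the surviving *m5C DEGs* into *gene
   clusters* A, B, C;
5. split the m5C DEGs by the sign of their association with the
   gene-cluster ordering into signatures A and B, prune each with a
   shadow-feature selector (`partition_signatures()`, `reduce_signatures()`);
6. score each sample as `PC1A - PC1B`, the difference of the first
   principal components of the two signatures (`compute_score()`);
7. dichotomize at the survival-optimal cutpoint and compare outcomes,
   immune context, immunotherapy response and predicted drug sensitivity
   between high and low score groups (`dichotomize()`, `km_fit()`,
   `response_analysis()`, `ridge_ic50()`).

`m5c_pipeline()` orchestrates all of it; every stage is also exported on
its own. Single-sample immune scoring (`ssgsea()`), ESTIMATE-style
stromal/immune composites (`estimate_scores()`) and the usual statistical
dispatch (`group_compare()`, `correlate()`) support the characterization
stages.

## The synthetic study cohort

Real cohorts of this design are assembled from multiple public consortia
and cannot be shipped or re-downloaded reproducibly. The package therefore
includes a first-class generator, `generate_cohort()`, whose **defaults are
the package's reference study conditions**, and whose planted ground truth
makes every stage falsifiable:

* **3 clusters x 100 tumor samples** across 3 batches, 2000 genes, plus 10
  normal samples per batch. Three hundred tumor samples is large enough for
  every stage to be well-powered yet keeps a full run around a minute; it
  is a scaled-down analogue of the hundreds-of-patients multi-cohort
  designs this workflow targets.
* **Regulator cluster structure**: each cluster shifts the 12 regulators by
  ±1.5 SD with a distinct sign pattern; patterns are centered per gene
  across clusters so cluster structure does not contaminate the
  tumor-vs-normal contrast.
* **Tumor-vs-normal shifts** of ±1 SD follow the reported direction per
  regulator (six up, four down, two null in tumors).
* **A latent prognostic level z** ~ Normal(cluster offset, 1), offsets
  evenly spaced in [-1, 1]. Signature-A genes rise with z (+0.5 SD per
  unit), signature-B genes fall; survival is exponential with rate
  `0.05 * exp(-0.8 z)` per month under Uniform(0, 60) censoring (about 60%
  events); responders (CR/PR) are drawn with probability `plogis(z)`.
  High z therefore means high score, longer survival and more responders —
  the direction the workflow is supposed to recover.
* **Immune blocks** (30 genes per cluster, +1 SD within their cluster)
  give the 24 immune-cell signature sets of `generate_gene_sets()`
  something real to detect; **stromal/immune blocks** follow an
  independent latent microenvironment level.
* **Batch effects**: non-reference batches get gene-wise additive shifts
  Normal(±0.8, 0.1²) and 1.3-fold residual variance inflation — larger
  than many of the biological effects, so merging without correction is
  visibly wrong.

What the generator does **not** emulate: count noise (negative binomial),
probe-level artifacts, gene-gene correlation beyond the planted blocks,
single-cell structure, or informative censoring. Passing tests on this
cohort demonstrate that the machinery recovers planted structure of
realistic effect size; they do not certify performance on any real
platform's noise.

The drug-sensitivity panel (`generate_reference_panel()`) plants, per drug,
a 10-gene sparse linear model of log-IC50 with a fixed 3:1 signal-to-noise
ratio on 300 cell lines x 100 genes. The panel is deliberately
overdetermined (lines well above genes), as in real pharmacogenomic panels;
with lines comparable to genes the noiseless ridge limit could not recover
the truth at all.

## Models and numerical choices

### Batch correction

`combat_correct()` implements the parametric empirical-Bayes location/scale
model for log-expression: standardize each gene against its batch-design
fit, estimate per-batch per-gene location and scale effects, shrink them
across genes within each batch (normal prior on location, inverse-gamma on
scale, hyperparameters by method of moments), and back-transform. Two
implementation details matter:

* variances use maximum-likelihood denominators (n pooled, n_b per batch),
  so duplicating a batch yields *exactly* the input back;
* a degenerate prior (zero across-gene spread of the location or scale
  estimates) shrinks completely to the prior mean rather than dividing by
  zero.

Shrinkage deliberately leaves per-gene sampling noise of batch means in
place — only the systematic (shared) batch shift is removed. The test
suite verifies agreement with the reference implementation to four decimal
places on all gap statistics. Genes constant within a batch have no
estimable scale effect and are dropped with a warning; no biological
covariates are protected in the design (cluster labels are computed only
after correction).

### Consensus clustering and the number of clusters

`consensus_cluster()` resamples `pItem` = 80% of samples `B` times, runs
k-means (k-means++ seeding, best of three restarts; average-linkage
hierarchical optional) and accumulates the co-cluster/co-sample ratio. The
multi-start seeding matters: a single random start leaves enough local-optimum
noise in the consensus matrix to distort the stability profile.

Two k-selection criteria are implemented. **PAC** (proportion of consensus
entries in (0.1, 0.9)) is minimized, ties toward the smaller k. **Delta
area** picks the largest k whose relative gain in area under the consensus
CDF exceeds 0.1 — the classical elbow rule, and the default. The reason
the elbow is the default is a real degeneracy: on cleanly nested planted
structure the consensus matrix is perfectly stable (PAC exactly 0) for
*every* k up to the true one, so PAC's smallest-k tie-break systematically
under-estimates k, while the CDF-area gain collapses precisely at the true
k. When even the best PAC exceeds 0.25 the selection carries a
low-confidence flag; the threshold separates structureless Gaussian data
(minimum PAC around 0.3-0.5) from planted structure (PAC near 0).
Clusters are named by descending mean feature expression, the only
convention that is reproducible across runs; never-co-sampled pairs get
consensus 0 and are counted.

### Moderated differential expression

`moderated_anova()` fits a one-way model per gene and shrinks residual
variances with the standard log-variance moment matching: the prior
degrees of freedom solve a trigamma equation (inverted by Newton
iteration), the prior variance follows from the digamma identity, and the
posterior variance `(d0 s0² + d s²)/(d0 + d)` forms the moderated F on
`(k-1, d0+d)` degrees of freedom. When the trigamma equation has no
solution the prior is infinite (complete shrinkage, with a warning); when
all observed variances are numerically identical the prior is a point mass
*at* that common value, so the moderated and classical F coincide exactly.
`prior_df = 0` is an explicit escape hatch to plain ANOVA. BH is the
default multiplicity adjustment for DEG calling; Bonferroni is available.

### ssGSEA and ESTIMATE

The enrichment statistic is the integrated difference between the
rank-weighted in-set ECDF (weight `rank^alpha`, alpha = 0.25, mid-ranks at
ties) and the unweighted out-of-set ECDF along the descending-expression
gene list. Ties in the walking order are broken by gene identifier so the
result is invariant to input ordering; being rank-based it is invariant to
any strictly increasing per-sample transform. Range normalization of the
score matrix is ON for the 24-cell immune matrix (cosmetic for the
rank-based downstream comparisons) and OFF for ESTIMATE, whose published
scale is unnormalized. Tumor purity applies the published cosine
calibration verbatim and flags samples whose argument leaves [0, pi]
(the calibration is platform-specific).

### Signatures, shadow selection and the score

"Positively correlated with gene cluster" needs a numeric encoding of the
cluster labels. The package encodes clusters by **descending mean observed
survival time** (best-outcome cluster gets the highest code; without
clinical data, reverse-alphabetical order), which makes the chain
"signature A high ⇒ good prognosis ⇒ high score ⇒ longer survival"
internally consistent. Spearman correlation against this encoding splits
the DEGs; constant genes fall to signature B with a warning.

`shadow_select()` follows the shadow-feature scheme: each iteration
appends an independently permuted copy of every candidate (at least five
shadows, so the benchmark stays honest when few candidates remain), fits a
random forest, scores a hit for candidates beating the best shadow, and
decides by two-sided binomial tests (chance ½) Bonferroni-corrected at
FWER 0.01. Tentative features are kept by default. Selection runs
separately within signatures A and B with the gene-cluster labels as
target. Note that an all-relevant selector will confirm any feature with a
*consistent* in-sample importance edge — including chance correlations in
small cohorts; this is inherent to the method, not a defect of the
implementation.

`compute_score()` z-scores each signature's genes, takes the first
principal component with the **loading-sum-positive** orientation (the
only way to make the sign of a principal component reproducible), and
returns `PC1A - PC1B` per sample; an empty signature B contributes zero.
`dichotomize()` scans every observed score value leaving at least
`ceiling(minprop * n)` samples per side (minprop = 0.1, the reference
default), computes the standardized two-group log-rank statistic, and cuts
at the maximizer, ties toward the lower cutpoint. One candidate suffices
(minprop = 0.5 with even n leaves exactly the median split); zero
candidates is an error.

### Survival, response and drug sensitivity

`km_fit()`/`logrank()` are the textbook product-limit estimator and
observed-minus-expected statistic with hypergeometric variance
(simultaneous-event tie convention; censored-at-event-time samples count
as at risk). The response table tests CR/PR vs SD/PD by high/low group
with Fisher's exact test, switching to Pearson chi-square only when every
expected count exceeds 5. `ridge_ic50()` z-scores the shared genes by the
*panel's* statistics (panel-anchored standardization in place of the
reference tool's quantile homogenization — the synthetic cohort is already
continuous), picks the penalty by 10-fold cross-validated MSE and solves
the ridge normal equations in closed form. Cox modeling is deliberately
absent: the workflow's claims are all KM/log-rank shaped.

## Problem sizes and runtime

The package's own test and acceptance runs use the default cohort (300
tumor + 30 normal samples, 2000 genes), consensus with B = 200 resampling
iterations per stratification (the `consensus_cluster()` default is
B = 1000; 200 already yields consensus matrices indistinguishable at these
separations and keeps a full pipeline run around a minute), 30
shadow-selection iterations per signature inside the pipeline, and a
300-line drug panel. A full `m5c_pipeline()` run on these sizes completes
in about one minute on a single CPU.

## Known limitations

* Gaussian log-intensity only; no count models (use the appropriate
  count-based tools upstream and hand the pipeline log-scale matrices).
* The external tumor-vs-normal DEG list is an input, not computed: with
  real data it would come from an external resource; the synthetic truth
  provides it for testing.
* TIDE, MSI, CAF and similar trained external scores are consumed as
  user-supplied tables and only correlated against the m5C score.
* The purity cosine calibration is platform-specific; out-of-band samples
  are flagged rather than extrapolated.
* Published full-scale cohort quantities (patient counts, exact DEG
  totals) depend on the original consortium downloads and are not
  reproducible at desk scale; the synthetic cohort reproduces the
  *structure* of every claim instead.
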