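# m5Cscope

Stratifying tumor cohorts by their RNA 5-methylcytosine (m5C) regulator
landscape — and scoring each patient's immune microenvironment and
prognosis from it.

## The problem

Twelve genes write, erase and read the m5C mark on RNA: the DNMT and NSUN
methyltransferase families, TRDMT1, and the YBX1/YBX2 readers. In
pancreatic adenocarcinoma and other tumors, the joint expression pattern of
these regulators separates patients into subgroups that differ in immune
cell infiltration, immunotherapy response and overall survival. Getting
from a pile of heterogeneous expression cohorts to that claim requires a
long chain of machinery — batch correction, resampled consensus
clustering, moderated differential expression, single-sample enrichment,
signature construction, survival-optimal dichotomization — each piece of
which is usually a different package with different conventions.

`m5Cscope` implements the whole chain as one tested, reusable pipeline for
analysts working with merged bulk expression cohorts (log2 scale) plus
clinical follow-up. Every stage is implemented in-package and verified
against independent oracles and planted ground truth.

## The core construction

Samples are consensus-clustered on the 12 regulators (resampling B
subsamples of 80% of samples; the number of clusters k chosen by the
consensus-CDF elbow over k = 2..9). Genes that differ across the resulting
m5C clusters (moderated F, adjusted p < 0.05) are intersected with an
external tumor-vs-normal DEG list; the survivors define gene clusters
A/B/C and are split by the sign of their Spearman association with the
survival-ordered gene-cluster encoding into **signature A** (positively
associated) and **signature B** (the rest), each pruned by a Boruta-style
shadow-feature selector. The per-sample score is

    m5C score_i = PC1A_i − PC1B_i

the difference between the first principal components of the two signature
blocks (z-scored genes, component sign fixed by the loading-sum-positive
rule). Patients split into high/low score groups at the cutpoint
maximizing the standardized two-group log-rank statistic (minimum group
proportion 0.1), and the groups are compared by Kaplan–Meier/log-rank,
CR/PR response rates, ESTIMATE-style stromal/immune composites and
ridge-predicted drug sensitivity (log-IC50 trained on a reference panel).

Because the real multi-consortium cohorts cannot be redistributed, the
package ships a synthetic-cohort generator (`generate_cohort()`) that
plants all of this structure — clusters, signatures, a latent prognostic
level driving exponential survival and logistic response labels, batch
effects, immune blocks — so the full pipeline is testable end to end.
See the vignette (`vignettes/m5c-workflow.Rmd`) for the models, defaults
and design decisions.

## Worked example

```r
library(m5Cscope)

cohort <- generate_cohort(sim_config(seed = 7))
cohort
#> synthetic_cohort: 300 tumor + 30 normal samples, 2000 genes, 3 planted clusters

sets <- generate_gene_sets(sim_config(seed = 7), seed = 8)
res <- m5c_pipeline(cohort$expression, cohort$clinical,
                    immune_sets = sets$immune,
                    external_degs = cohort$truth$tumor_deg_genes,
                    run_shadow = FALSE, seed = 9)

res$manifest$counts[c("k_m5c", "n_cluster_degs", "n_m5c_degs")]
#> $k_m5c
#> [1] 3
#> $n_cluster_degs
#> [1] 231
#> $n_m5c_degs
#> [1] 130

res$survival$by_score
#> km_fit with 2 group(s); median survival: high = 17.74, low = 2.87
#>   log-rank chi2 = 120.926, df = 1, p = 3.97e-28

res$response$rates
#>      high       low
#> 0.5708155 0.2089552
```

Reading the output: the pipeline re-identifies the three planted regulator
clusters (`k_m5c = 3`), finds 231 genes differing across them of which 130
survive the external-list intersection, and the resulting score splits the
cohort into groups whose median survival differs six-fold (17.7 vs 2.9
months, log-rank p ≈ 4e-28) with a CR/PR immunotherapy response rate of
57% in the high-score group versus 21% in the low — the planted
high-score-better-outcome structure, recovered from expression alone.
Columns `pc1a`, `pc1b`, `m5c_score` and `group` per sample sit in
`res$score`.

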