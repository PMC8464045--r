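# surftf

**surftf** links cell-surface receptor signaling to downstream
transcription-factor (TF) activity in CITE-seq data, where each cell is
profiled for both its transcriptome (scRNA-seq UMI counts) and a panel of
surface proteins (antibody-derived tags, ADTs). It is aimed at
immunologists and computational biologists who want per-cell TF activity
estimates that are informed by surface phenotype — e.g. which TFs couple
to PD-1 or CD27 expression within a T-cell subset — rather than by
expression alone.

## The model

With `Y` (genes × cells) the normalized expression matrix, `D` (genes ×
TFs) a binary TF→target regulon prior, and `P` (cells × proteins) the
CLR-normalized ADT matrix, surftf fits the bilinear affinity regression

```
D W Pᵀ ≈ Y
```

for the TF × protein interaction matrix `W`, by elastic-net regression on
the Yᵀ-compressed Kronecker system

```
min_W ‖vec(YᵀY) − (P ⊗ YᵀD) vec(W)‖₂² + λ₂‖W‖₂² + λ₁‖W‖₁
```

with an optional SVD reduction of `P` for wide panels. The trained `W`
yields two per-cell read-outs: TF activities `W Pᵀ` and projected
surface-protein activities `Yᵀ D W`. Significance of TF activities is
assessed against an empirical null built by permuting gene labels of `Y`
and retraining; predictive quality is benchmarked against a
nearest-neighbour-in-protein-space baseline with a one-sided Wilcoxon
signed-rank test.

## Worked example

Everything below runs on synthetic data from the package's own generator
(no downloads). `generate_instance()` plants a ground-truth `W*` and
emulates raw counts; real data would instead enter through
`read_counts()`, `qc_filter_cells()`, `log_normalize_rna()` and
`clr_normalize_adt()`.

```r
library(surftf)

cfg  <- sim_config(n_genes = 200, n_cells = 100, n_tfs = 20,
                   n_proteins = 10, prior_density = 0.1, snr = 10, seed = 1)
inst <- generate_instance(cfg)

# align shared genes/cells and unit-normalize all columns (as training requires)
al <- align_and_unit_normalize(inst$Y, inst$P_latent, inst$D)

cv <- cross_validate(al$Y, al$D, al$P,
                     grid = expand.grid(lambda1 = 0,
                                        lambda2 = c(1e-3, 1e-2, 1e-1)),
                     folds = 5, seed = 1)
cv
#> <cv_result> 5-fold CV over 3 grid points | best lambda1=0 lambda2=0.001 (mean rho 0.869)

model <- fit_affinity(al$Y, al$D, al$P, lambda2 = cv$best$lambda2)
model
#> <affinity_model> 20 TFs x 10 proteins | lambda1=0 lambda2=0.001 | 0% zeros
cor(as.vector(model$W), as.vector(inst$W_star))
#> [1] 0.897

# a sparse variant of the same fit
sys <- build_reduced_system(al$Y, al$D, al$P)
solve_elastic_net(sys, lambda1 = 0.3 * lambda_max(sys),
                  lambda2 = cv$best$lambda2)
#> <affinity_model> 20 TFs x 10 proteins | lambda1=112.354 lambda2=0.001 | 96% zeros

# per-cell TF activities and permutation significance
act  <- infer_tf_activity(model, al$P, zscore = TRUE)
null <- build_null_model(al$Y, al$D, al$P, n_perm = 1000, seed = 1,
                         lambda2 = cv$best$lambda2)
score_significance(act, null)
#> <significance_report> 2000 (TF, cell) tests | 1000 permutations | alpha=0.15 | 42 significant

# held-out prediction vs the nearest-neighbour baseline
evaluate_methods_cv(al$Y, al$D, al$P, lambda2 = cv$best$lambda2,
                    folds = 5, seed = 1)
#> <method_comparison> mean rho: affinity 0.869 vs nearest-neighbor 0.751 | one-sided Wilcoxon p = 3.11e-18
```

Reading the numbers: the cross-validated model predicts held-out
expression at mean per-cell Spearman ρ ≈ 0.87 and recovers the planted
interaction matrix at correlation 0.90; it significantly outperforms
copying the most protein-similar training cell (ρ ≈ 0.75, p ≈ 3e-18);
and 42 of 2000 (TF, cell) activities exceed the gene-permutation null at
Bonferroni-adjusted p < 0.15. Fitted models are tidyverse-friendly:
`tidy(model)` gives the long (tf, protein, weight) table, `glance(model)`
the one-row summary, `autoplot(model)` a weight heatmap.

Association tooling — `tf_protein_correlation()`, `enrichment_test()`
(hypergeometric pathway co-occurrence of correlated TF–protein pairs),
`cluster_cells_by_protein()` (Ward/correlation clustering with
differential-marker refinement) and `differential_activity()` — is
demonstrated in the vignette (`vignettes/affinity-regression.Rmd`),
along with every modelling decision and default.

A thin command-line wrapper for train/infer/simulate lives at
`inst/cli/surftf.R`.

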