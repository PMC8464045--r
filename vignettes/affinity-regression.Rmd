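---
title: "Bilinear affinity regression for CITE-seq: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilinear affinity regression for CITE-seq: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surftf)
```

## The model

CITE-seq measures, in the same cell, the transcriptome (UMI counts over
genes) and the abundance of selected surface proteins (antibody-derived
tags, ADTs). `surftf` couples the two measurements through a prior on
transcription-factor (TF) regulons: with

* \(Y \in \mathbb{R}^{N \times M}\) — normalized expression, genes × cells,
* \(D \in \{0,1\}^{N \times Q}\) — regulon membership, genes × TFs
  (unsigned: activator/repressor direction is not represented),
* \(P \in \mathbb{R}^{M \times S}\) — normalized ADT values, cells ×
  proteins,

the bilinear ("affinity") regression model is

\[ D\, W\, P^{T} \approx Y, \]

where \(W \in \mathbb{R}^{Q \times S}\) is the learned interaction matrix
between TFs and surface proteins. A cell's expected expression is the sum
of regulon signatures, weighted by how its surface-protein profile couples
to each TF. Once \(W\) is trained, two linear *mappings* give the
biological read-outs per cell:

* TF activities: \(A_{TF} = W P^{T}\) (TFs × cells) —
  `infer_tf_activity()`;
* projected surface-protein activities: \(A_{prot} = Y^{T} D W\) (cells ×
  proteins) — `infer_protein_activity()`.

## Solving the regression

Vectorizing, \(D W P^T \approx Y \iff (P \otimes D)\,\mathrm{vec}(W)
\approx \mathrm{vec}(Y)\). Because \(N\) and \(M\) are large, both sides
are compressed by \(Y^T\):

\[ (P \otimes Y^{T} D)\,\mathrm{vec}(W) \approx \mathrm{vec}(Y^{T} Y), \]

a system whose row dimension is \(M^2\) instead of \(N M\), and whose
Gram matrix factorizes as \((P^{T}P) \otimes (G^{T}G)\) with
\(G = Y^{T} D\). The regularized objective is the elastic net

\[ \min_W \left\| \mathrm{vec}(Y^T Y) - (P \otimes G)\,\mathrm{vec}(W)
\right\|_2^2 + \lambda_2 \|W\|_2^2 + \lambda_1 \|W\|_1 . \]

Implementation notes:

* **Ridge path (\(\lambda_1 = 0\))** is solved in closed form through
  eigendecompositions of the two Gram blocks (`solve_ridge_reduced()`);
  the Kronecker structure makes the normal equations decouple in the
  joint eigenbasis. Components along numerically-zero eigendirections are
  set to zero exactly — this reproduces the exact-arithmetic limit and
  keeps tiny \(\lambda_2\) (down to \(10^{-10}\)) from amplifying
  floating-point residue when \(Y\) is rank-deficient.
* **Elastic net (\(\lambda_1 > 0\))** uses deterministic cyclic coordinate
  descent with precomputed Gram blocks (`solve_elastic_net()`). The sweep
  stops when the largest coefficient update falls below
  `tol * (1 + max|W|)` (default `tol = 1e-8`, `max_iter = 10000` sweeps);
  the convex objective is non-increasing across sweeps and is reported in
  the fitted object. The all-zero solution is optimal exactly at
  \(\lambda_1 \ge 2\|A^T b\|_\infty\), exposed as `lambda_max()`.
* **SVD reduction of P.** For wide ADT panels, `build_reduced_system()`
  can replace \(P\) by its rank-\(k\) truncation (smallest \(k\) whose
  cumulative squared singular values reach `var_retained`, default 0.95).
  The L1 penalty is always applied to \(W\) in *original* protein
  coordinates (L1 is not rotation invariant), so `var_retained = 1` is
  exactly equivalent to no reduction; for ridge the two routes are
  algebraically identical. \(W\) is always reported in original protein
  coordinates.
* **Identifiability.** The compressed design determines \(W\) only on the
  subspace visible to \(Y\): if \(Y\) is exactly rank-deficient (e.g. a
  noise-free bilinear instance with more TFs than proteins,
  \(\mathrm{rank}(Y^T D) \le S < Q\)), the invisible directions are
  returned as zero. Any noise in \(Y\) restores full identifiability; the
  exact-recovery checks in the test suite therefore use instances with
  \(Q \le S\) for the noise-free limit.

Hyperparameters are chosen by `cross_validate()`: seeded shuffle of cells
into folds (default 5), score = mean per-cell Spearman correlation between
\(\hat Y = D W P_{test}^T\) and the measured held-out expression, ties
broken toward larger \(\lambda_1\) then larger \(\lambda_2\) (the sparser,
smoother model). The default grid is log-spaced \(10^{-4} \dots 1\) per
axis. Note the penalties act on a fixed scale only because the training
pipeline unit-normalizes all columns (below); on unnormalized data the
Gram spectrum dwarfs any \(\lambda\) in that range.

## Preprocessing

`read_counts()` reads CellRanger-style MTX triplets or dense CSV/TSV.
The pipeline then applies, in order:

1. `qc_filter_cells()` — keep cells with an expressed-gene count \(g\)
   satisfying \(300 \le g \le 5000\) (inclusive bounds; the low cut
   removes debris/empty droplets, the high cut likely doublets).
2. `log_normalize_rna()` — \(\ln(1 + 10^4\, c_{gj}/T_j)\) per entry, a
   size factor of 10,000 molecules per cell; invariant to uniform
   rescaling of a cell's counts.
3. `clr_normalize_adt()` — centered log-ratio per protein **across
   cells**: \(\mathrm{clr}_{ij} = \ln(1+x_{ij}) - \mathrm{mean}_{j'}
   \ln(1+x_{ij'})\), giving the testable invariant that every protein's
   mean over cells is exactly 0. A `method = "seurat"` flag reproduces the
   log1p/geometric-mean variant used by Seurat, which lacks that
   invariant.
4. `build_prior_matrix()` — binary regulon matrix over the measured gene
   universe; TFs without expressed targets are dropped, duplicate edges
   collapse to 1.
5. `align_and_unit_normalize()` — restrict to shared cells and genes and
   divide every column of \(Y\), \(P\) and \(D\) by its L2 norm (numerical
   stability and penalty scaling); all-zero columns are dropped with
   dependent bookkeeping.

Cell-type labels are an *input* (barcode → label); models are trained per
cell type. An optional gene-prevalence filter (≥3 UMIs in ≥1% of cells) is
available but off by default.

## Significance of TF activities

`build_null_model()` permutes the **gene labels (rows)** of \(Y\) —
breaking the correspondence between expression and the regulon prior while
preserving each cell's expression distribution — retrains \(W\) with the
same hyperparameters, and records null activities \(W_r P^T\). Permuting
cells instead would leave part of the \(Y^T D\) structure intact; the axis
is still exposed via `perm_axis` for diagnostics. \(Y^T Y\) is invariant
under row permutation and the SVD of \(P\) is unchanged, so each
permutation costs only one \(Y^T D\) product and one closed-form ridge
solve.

`score_significance()` computes two-tailed empirical p-values with the +1
correction, \(p = \min(1,\, 2\min(p_{lo}, p_{hi}))\),
\(p_{tail} = (b+1)/(n_{perm}+1)\) — so p is never 0 and lives on
\([1/(n_{perm}+1), 1]\) — then Bonferroni-corrects across TFs within each
cell (calls at adjusted \(p < 0.15\) by default) and reports per-TF
frequencies (fraction of cells significant, optionally per cell type), BH
q-values as an extra column, and the direction of the deviation. The
desk-scale default is 200 permutations; 5000 (as used on real data)
is a parameter. With \(Q\) TFs the smallest attainable adjusted p is
\(2Q/(n_{perm}+1)\); a warning fires when that already exceeds the
threshold.

## Evaluation

`evaluate_methods_cv()` scores the model against a nearest-neighbour
baseline under the same fold split: each test cell is predicted by the
expression profile of the training cell closest in Euclidean distance in
surface-protein space (ties to the lowest training index). Per-cell
Spearman correlations (average-rank ties; zero-variance cells recorded as
NA and excluded from means) are compared by a one-sided Wilcoxon
signed-rank test — exact by sign-flip enumeration (dynamic programming
over doubled ranks, valid under ties) for ≤25 informative pairs, normal
approximation with continuity correction beyond.

## Association analyses

* `tf_protein_correlation()` — Pearson r between each inferred TF activity
  and each measured protein across cells of a cell type.
* `enrichment_test()` — pairs with \(|r| > 0.4\) are "correlated", pairs
  with \(|r| < 0.2\) "uncorrelated"; the intermediate band is excluded (the
  two-class definition implies it). The 2×2 table against shares-a-pathway
  membership (from a GMT file via `pathway_cooccurrence()`, with an
  editable ADT→gene alias table, e.g. CD279→PDCD1) is tested by the
  upper-tail hypergeometric probability — identical to Fisher's one-sided
  exact test, which the test suite uses as the oracle.
* `cluster_cells_by_protein()` — Ward D2 linkage on correlation distance
  \(1 - r\) between cells, initial cut into 10 groups, then iterative
  re-cuts with one fewer group until every **pair** of clusters differs in
  at least 2 proteins (pairwise Wilcoxon rank-sum per protein, BH-FDR <
  0.05 across proteins). The pairwise form of the qualification is
  deliberate: requiring markers against the pooled rest can never merge
  sub-clusters of a genuinely distinct group, because such sub-clusters
  inherit the group's markers against everything else; pairwise testing
  merges exactly the indistinguishable splits. Bootstrap-based cluster
  probabilities are intentionally not reproduced — the dendrogram plus the
  differential-marker rule is deterministic and testable. Cluster ids are
  canonicalized (decreasing size, then smallest member barcode) so the
  partition is invariant to cell input order. The reported differential
  table compares each final cluster against all other cells
  (`differential_activity()` does the same for TF activities, with effect
  size = difference of means and BH-FDR across TFs within each cluster).

## Synthetic data

`generate_instance()` draws the structure the model assumes: \(D \sim\)
Bernoulli(`prior_density`) with at least one target per TF, dense Gaussian
\(W^*\) (optionally sparsified), non-negative latent proteins \(P =
|\mathcal{N}(0,1)|\), and \(Y = D W^* P^T + \varepsilon\) with the noise SD
set directly or from a target signal-to-noise ratio
\(\mathrm{SNR} = \|Y_{clean}\|_F^2 / E\|\varepsilon\|_F^2\). Raw counts
invert the normalizations so the I/O path is testable end to end: RNA
counts are multinomial per cell at `count_depth` with probabilities given
by the softmax of the cell's *z-scored* expression column (z-scoring keeps
the dynamic range sampleable; raw softmax would concentrate essentially
all mass on a handful of genes and destroy rank fidelity), and ADT counts
are Poisson around depth-scaled \(\exp(P)\). `generate_null_instance()`
replaces \(Y\) by pure noise for calibration studies. Everything is a pure
function of the `sim_config()`, including the seed.

What the generator does **not** emulate: dropout beyond what multinomial
thinning produces, overdispersion (negative-binomial counts are a config
extension, not the default), batch effects, doublets, or realistic
cell-type proportions. Passing tests on this generator demonstrate the
estimator and its calibration under the model's own assumptions, not
robustness to real-data artifacts.

## Problem sizes and defaults

The shipped tests and the reproduction script run at desk scale, chosen so
the full suite completes in seconds while keeping every check
well-powered: 200 genes × 100 cells × 20 TFs × 10 proteins for recovery
and baseline comparisons (SNR 10 and 5), 50 cells × 200 permutations for
null calibration, 30 cells × 40 proteins with 3 planted markers for
cluster refinement, and 20 random instances with \(QS \le 200\) for the
brute-force Kronecker oracle. Fits on these sizes take milliseconds; real
CITE-seq panels (thousands of cells, 50–200 ADTs) run in seconds to
minutes with the SVD reduction.

Defaults worth knowing: `lambda2 = 1e-3` (on unit-normalized inputs),
`var_retained = 0.95`, `folds = 5`, `n_perm = 200`, `alpha = 0.15`
(Bonferroni-adjusted), enrichment thresholds 0.4/0.2, `init_groups = 10`,
`min_markers = 2`, FDR 0.05.

## Known limitations

The regulon prior is unsigned and noisy; inferred activities are linear
read-outs and inherit its errors. TF–TF cooperativity and receptor
crosstalk are not modelled. The permutation null retrains with the
observed hyperparameters (re-selection per permutation is possible but
costly and changes the null's meaning). Wilcoxon-based differential tables
use the unpaired rank-sum form for cluster-vs-rest comparisons, which is
the form the group structure calls for.
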