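---
title: "Methods: tree-guided multi-task inference of TF activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-guided multi-task inference of TF activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeguide)
```

## Model and assumptions

`treeguide` treats every cell of a single-cell expression matrix as one
task of a multi-task linear regression. For `n` genes, `p` TF features
and `k` cells, the model is `Y = XB + ε` with Gaussian errors on the
log2 scale: responses are log2(TPM + 1) and features are log2(score + 1)
of nonnegative TF scores. The estimate minimises an un-halved residual
sum of squares plus a tree-structured group-lasso penalty: for each
feature row `β^j` of `B` and each node `v` of a rooted tree over the
cells, the term `w_v ||β^j_{G_v}||₂` couples the cells below `v`. Nested
groups mean a TF can be switched off for all cells, for a subtree (a cell
type), or tuned per cell; the root group gives joint row sparsity, the
leaf groups elementwise sparsity.

Underlying assumptions worth stating explicitly:

* expression is approximately Gaussian after the log2 transform — counts
  and dropout are not modelled (a negative-binomial treatment is a known
  limitation, not a goal here);
* the feature matrix is informative about expression in *trans*-free
  fashion: features are computed per gene from sequence/epigenome and are
  identical across cells, so all cell specificity lives in `B`;
* genes are exchangeable observations: the train/test split and CV folds
  are over genes, never over cells, because cells are the tasks.

## The task tree

Four constructions are provided. `build_hc_tree()` applies complete
linkage to the dissimilarity `1 − Pearson(cell_i, cell_j)` computed
across genes and keeps every binary merge node. `build_embedding_tree()`
applies the same agglomeration to externally supplied 2-D cell
coordinates (e.g. a pseudotime embedding). Here we deliberately use the
Euclidean distance rather than `1 − cor`: correlation between cells over
only two coordinates is degenerate (it takes essentially the values ±1),
while a metric distance separates distant point clouds first, which is
the behaviour a trajectory-derived tree is meant to capture.
`build_star_tree()` is the no-structure baseline (root plus `k` leaves).
The randomised control refits the whole model on expression shuffled
within each cell (`shuffle_expression()`), preserving each cell's value
multiset exactly; the tree is then rebuilt from the shuffled matrix.

Node weights are not fully pinned down by the original description
("typically the depth of the subtree"); we define `w_v` as the height of
the subtree rooted at `v` counted in nodes, so leaves weigh 1 and the
root weighs most, with an optional normalisation by the root height.
This keeps weights positive, integer-valued and monotone up the tree,
and reproduces the stated star-tree anchor (leaf weight 1, root
weight 2).

## Optimisation

The penalty's groups form a laminar family, so the proximal operator of
`τ Σ_v w_v ||·_{G_v}||₂` is exact: one pass of group soft-thresholding
ordered leaves-to-root. The solver is FISTA with step size `1/L`, where
`L = 2 λ_max(XᵀX)` is computed by a dense symmetric eigendecomposition
(p is at most a few hundred here). A monotone safeguard rejects any
accelerated step that would raise the objective and falls back to a
plain proximal-gradient step from the last accepted iterate, which
cannot increase the objective at this step size; the recorded objective
log is therefore nonincreasing by construction, and the fit errors out
if that invariant is ever violated beyond 1e-12 relative slack.

Numerical choices: stopping at relative objective change below
`tol = 1e-6` (configurable), at most 1000 iterations by default;
`λ = 0` is solved by the same iteration (no closed-form shortcut) so the
unpenalized limit genuinely tests the solver; `lambda_max_tree()` gives
the KKT-derived bound `max_j 2||(XᵀY)^j||₂ / w_root` above which `B = 0`
is provably optimal (the penalty of each row dominates its root term).
Cross-validation minimises validation MSE pooled over tasks — the CV
loss is not named in the original description, and pooled MSE is the
natural choice when one global `λ` couples all tasks (a per-task `λ` is
not meaningful under a penalty that spans tasks). Ties select the
smaller `λ`. Fold assignment is seeded and recorded.

The ordinary multi-task baseline implements the printed objective — RSS
plus `α Σ_j ||β^j||₂` — with the same solver (the penalty is the special
case of a single all-tasks group). The surrounding text calls this model
"elastic net"; an optional ridge term is exposed for that reading, but
the default is the printed form. The single-task baseline is glmnet's
elastic net per cell with `α ∈ {0, 0.1, …, 1}` and shared CV folds.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| promoter half-window | 1000 | bp | 2 kb window centred at the TSS |
| open-chromatin half-window | 25000 | bp | 50 kb regulatory neighbourhood |
| ChIP half-window | 1500 | bp | 3 kb window around the TSS |
| decay constant `d0` | 5000 | bp | exponential decay of peak influence |
| TRAP energy scale `λ` | 0.7 | — | published biophysical default |
| TRAP `ln R0` | `0.584·L − 5.66` | — | published length calibration |
| PWM pseudocount | 0.01 | counts | avoids log(0) in log-odds |
| detection threshold | 0.1 | TPM | detected-gene rule |
| detecting cells | 10 | cells | detected-gene rule |
| log2 pseudocount | 1 | — | maps 0 to 0; value not stated upstream |
| train fraction | 0.6 | — | 60/40 gene split |
| λ grid | 0…1 step 0.05 | — | 21 CV candidates |
| max iterations | 1000 | — | solver budget |
| heat-map threshold | 0.5 | Σ\|coef\| | TF display selection |
| BH significance | 0.1 | — | differential-activity cut-off |

Coordinates are 0-based half-open everywhere; windows are
`[tss − half, tss + half)`, and a peak ending exactly at a window start
does not overlap it. The third-quartile threshold of the feature-variance
filter uses the type-7 (linear interpolation) quantile — the kept gene
set depends on this convention, so it is fixed and documented. Peak
affinities for the open-chromatin features are computed on the whole
peak even when the peak only partly overlaps the window (motif context
should not be truncated), while `Peak_Length` counts only the
overlapping base pairs (window property); the upstream description does
not resolve this, so the choice is flagged here. ChIP "counts" are taken
as a user-supplied per-peak count column.

## Interpretation statistics

`select_heatmap_tfs()` keeps TFs with Σ|coef| strictly above 0.5.
`rank_tf_activity()` scales each cell's column by its maximum absolute
value before summing ("scaled coefficients" are unspecified upstream;
max-abs bounds each cell's contribution comparably, analogous to a
bounded per-cell AUC; `none` and `zscore` are available).
`differential_activity()` is a two-sided Mann–Whitney test per TF with
BH step-up across TFs; exact p-values for small tie-free samples, normal
approximation with continuity correction under ties (coefficient rows
with many exact zeros tie heavily). `tf_expr_cor()` is tied-rank
Spearman between a TF's expression and its coefficient row. The
permutation null pools the correlations of the shuffled-expression model
and removes real values inside `[min, max]` of that pool — the range,
not quantiles, because the upstream rule removes values "within the
range"; pooling across TFs follows the same reading. The sign filter
keeps a TF only when `sign(ρ) · sign(Σ_j B^j) > 0`: the printed version
of this rule multiplies a vector by a scalar, so the package implements
the textual description (sign agreement), and zeros on either side
discard the TF.

## What the synthetic data does and does not emulate

`generate_regression_fixture()` states the world the acceptance tests
measure: nonnegative folded-normal features (right-skewed, like binding
affinities), a block coefficient matrix with `n_clusters = 2` clusters
of 20 cells and 5 active TFs each at effect size 1, Gaussian noise with
`noise_sd = 0.1`, and a TF-expression matrix in which each planted TF is
elevated in its own cluster (so the sign filter has a defined truth).
Defaults are `n = 500, p = 50, k = 40`, small enough for the convex
oracle used in testing. `generate_tpm_fixture()` produces log-normal TPM
with Bernoulli dropout and genes built to fail the detection rule.
`generate_genomic_fixture()` plants exact motif consensi downstream of
known TSSs and scrubs chance occurrences of that motif elsewhere, so
"planted beats background" holds by construction.

None of these emulate real scRNA-seq count noise, library-size effects,
batch structure, or correlated features; a green recovery test
establishes that the estimator and its interpretation chain work when
the model's own assumptions hold, not that they would recover biology
from a particular real data set. Generator parameters are fixed once and
are never tuned against test outcomes.

## Known limitations

* Gaussian likelihood on log2 TPM; no count model, no imputation
  (an externally imputed matrix is accepted as input).
* One global `λ` for all tasks.
* The embedding tree requires externally computed coordinates;
  pseudotime inference itself is out of scope.
* Tie-breaking in agglomeration is delegated to `stats::hclust`;
  dissimilarity ties can reorder merges without changing heights.
* The Mann–Whitney test falls back to a normal approximation under
  heavy ties, where exact enumeration is not available.
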