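# treeguide

Tree-guided multi-task inference of transcription-factor (TF) activity
from single-cell gene expression.

## The problem

Single-cell RNA-seq measures thousands of genes across hundreds of cells,
and a central question is which TFs drive the expression differences
between cells and cell types. Regulon-scoring tools infer TF activity from
the co-expression of a TF's known targets, which restricts them to
positive associations and to well-annotated TFs. `treeguide` takes the
regression route instead: it predicts each cell's gene expression from
per-gene TF features that are independent of the expression data —
biophysical binding affinities at promoters, affinities inside
open-chromatin peaks, or ChIP-seq read counts near the TSS — and reads the
fitted coefficients as signed, cell-specific TF activities.

## The model

Let `X ∈ R^{n×p}` hold `p` TF features for `n` genes and `Y ∈ R^{n×k}`
the (log2 TPM) expression of those genes in `k` cells. Each cell is one
task of a multi-task linear model `Y = XB + ε` with coefficients
`B ∈ R^{p×k}`. Because related cells should use related regulators, a
rooted tree `T` over the cells (from hierarchical clustering of the
expression matrix, a 2-D embedding, or a star as baseline) defines the
tree-guided group-lasso estimate

```
B* = argmin_B  Σ_i ||y_i − Xβ_i||²  +  λ Σ_j Σ_{v∈V(T)} w_v ||β^j_{G_v}||₂
```

where `G_v` is the set of cells below node `v` and `w_v` the height of
the subtree at `v`. The groups of a rooted tree are laminar (any two are
disjoint or nested), so the penalty's proximal operator is computed
exactly by a single leaves-to-root pass of group soft-thresholding, and
the objective is minimised by accelerated proximal gradient descent
(FISTA) with a monotone safeguard. `λ` is chosen by gene-wise 5-fold
cross-validation over 21 values spanning [0, 1] at step 0.05. Single-task
elastic-net models (one per cell, via glmnet) and an ordinary multi-task
row group lasso are provided as baselines.

Downstream, the coefficient matrix is interpreted per TF: heat-map
selection (Σ|coef| > 0.5), activity ranking by summed max-abs-scaled
coefficients, two-sided Mann–Whitney tests between cell types with
Benjamini–Hochberg correction, Spearman correlation between a TF's own
expression and its inferred activity, a permutation null obtained by
refitting on shuffled expression, and a sign-consistency filter.

## Worked example

All inputs are synthesised by the package's seeded generators; no
external data is needed.

```r
library(treeguide)

fx <- generate_regression_fixture(n = 300, p = 30, k = 20, n_clusters = 2,
                                  tfs_per_cluster = 3, seed = 42)
split <- split_train_test(nrow(fx$X$values), seed = 42)
st <- standardize(fx$X$values, fx$Y$values, split$train)
tree <- build_hc_tree(fx$Y)
cv <- cross_validate_tree(st$X[split$train, ], st$Y[split$train, ], tree,
                          folds = 5, seed = 43)
fit <- fit_tree_guided(st$X[split$train, ], st$Y[split$train, ], tree,
                       cv$selected)
pred <- destandardize_response(st, st$X[split$test, ] %*% fit$B)
r <- evaluate_per_cell(pred, fx$Y$values[split$test, colnames(st$Y)])
median(r)
rep_ <- activity_report(fit, cell_labels = fx$Y$cell_labels,
                        tf_expression = fx$tf_expression)
```

This prints (abridged):

```
<CvResult> 21 lambdas, selected 0.25 (mean loss 0.01115)
<tg_fit> tree model: 30 features x 20 tasks, lambda=0.25 (12 iter, converged)
median held-out per-cell Pearson r: 0.996
heat-map TFs: TF01 TF02 TF03 TF04 TF05 TF06
    tf summed_abs_coef diff_p_adj tf_expr_cor sign_agrees
1 TF01            6.15   6.28e-05       0.701        TRUE
3 TF03            6.26   6.28e-05       0.800        TRUE
```

The six planted cluster-specific TFs are exactly the ones selected for
the heat map; each is significantly differentially active between the two
cell clusters (BH-adjusted Mann–Whitney p ≪ 0.1), its activity correlates
with its own expression across cells, and the correlation sign agrees
with the sign of its summed coefficients. The median held-out per-cell
Pearson correlation of 0.996 reflects the low-noise synthetic regime.

The same chain runs from a JSON config via
`run_pipeline(read_config("cfg.json"), out_dir = "out")` or the CLI
`Rscript -e 'treeguide::treeguide_cli()' run --config cfg.json --out out`,
which writes the coefficient matrix, evaluation, activity report, tree
(Newick + weight sidecar), split and run log as plain text.

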