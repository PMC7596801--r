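#' Select TFs for heat-map display
#'
#' Keeps a TF when the sum of absolute regression coefficients across all
#' cells is strictly greater than the threshold (default 0.5); a row
#' summing exactly to the threshold is discarded.
#'
#' @param B Coefficient matrix, TFs/features in rows, cells in columns.
#' @param threshold Strictly exceeded sum of |coefficients|; default 0.5.
#' @return Character vector of kept TF ids.
#' @export
select_heatmap_tfs <- function(B, threshold = 0.5) {
  B <- as.matrix(B)
  if (is.null(rownames(B))) stop("B needs TF row names")
  rownames(B)[rowSums(abs(B)) > threshold]
}

#' Rank TFs by summed (scaled) activity across cells
#'
#' Each cell's coefficient column is optionally scaled, then per-TF
#' activities are summed across cells and TFs are ordered by decreasing
#' activity. The default `maxabs` scaling divides every column by its
#' maximum absolute value so that each cell contributes on a comparable,
#' bounded scale. Ties are broken deterministically by TF id.
#'
#' @inheritParams select_heatmap_tfs
#' @param scaling `"maxabs"` (default), `"zscore"` or `"none"`.
#' @param top Optional number of top TFs to return (e.g. 20).
#' @return Data frame with `tf`, `activity` and `rank`, ordered by rank.
#' @export
rank_tf_activity <- function(B, scaling = c("maxabs", "zscore", "none"),
                             top = NULL) {
  scaling <- match.arg(scaling)
  B <- as.matrix(B)
  if (is.null(rownames(B))) stop("B needs TF row names")
  S <- switch(scaling,
    maxabs = apply(B, 2L, function(col) {
      m <- max(abs(col))
      if (m == 0) col else col / m
    }),
    zscore = apply(B, 2L, function(col) {
      s <- stats::sd(col)
      if (s == 0) col - mean(col) else (col - mean(col)) / s
    }),
    none = B)
  S <- matrix(S, nrow = nrow(B), dimnames = dimnames(B))
  activity <- rowSums(S)
  ord <- order(-activity, rownames(B))
  out <- data.frame(tf = rownames(B)[ord], activity = activity[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Differential TF activity between two cell types
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per TF on the
#' coefficients grouped by cell type, with Benjamini-Hochberg step-up
#' correction across TFs; exact p-values are used for small tie-free
#' samples and the normal approximation (continuity corrected) otherwise.
#'
#' @inheritParams select_heatmap_tfs
#' @param cell_labels Factor/character vector (named by cell, or in column
#'   order) with exactly two levels.
#' @param sig_level BH-adjusted significance cut-off; default 0.1.
#' @return Data frame with `tf`, `U`, `p_raw`, `p_adj`, `significant`.
#' @export
differential_activity <- function(B, cell_labels, sig_level = 0.1) {
  B <- as.matrix(B)
  if (is.null(rownames(B))) stop("B needs TF row names")
  if (!is.null(names(cell_labels)) && !is.null(colnames(B)))
    cell_labels <- cell_labels[colnames(B)]
  g <- factor(as.character(cell_labels))
  if (nlevels(g) != 2L) stop("exactly two cell types are required")
  if (any(table(g) < 2L)) stop("each cell type needs at least 2 cells")
  res <- t(vapply(seq_len(nrow(B)), function(i) {
    wt <- suppressWarnings(
      stats::wilcox.test(B[i, g == levels(g)[1L]],
                         B[i, g == levels(g)[2L]],
                         alternative = "two.sided"))
    c(U = unname(wt$statistic), p = wt$p.value)
  }, c(U = 0, p = 0)))
  p_adj <- stats::p.adjust(res[, "p"], method = "BH")
  data.frame(tf = rownames(B), U = res[, "U"], p_raw = res[, "p"],
             p_adj = p_adj, significant = p_adj <= sig_level,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation between TF expression and inferred activity
#'
#' For every TF, the Spearman correlation (average ranks under ties)
#' across cells between the TF's own expression and its coefficient row.
#' A constant coefficient or expression row yields `NA`.
#'
#' @inheritParams select_heatmap_tfs
#' @param tf_expression Matrix of log2 TPM values, same TF rows and cell
#'   columns as `B`.
#' @return Named numeric vector of correlations in \[-1, 1\] (or `NA`).
#' @export
tf_expr_cor <- function(B, tf_expression) {
  B <- as.matrix(B); E <- as.matrix(tf_expression)
  if (is.null(rownames(B))) stop("B needs TF row names")
  if (!all(rownames(B) %in% rownames(E)))
    stop("tf_expression lacks rows for some TFs")
  E <- E[rownames(B), colnames(B), drop = FALSE]
  if (ncol(B) < 3L) stop("need at least 3 cells")
  rho <- vapply(seq_len(nrow(B)), function(i) {
    if (stats::sd(B[i, ]) == 0 || stats::sd(E[i, ]) == 0)
      return(NA_real_)
    stats::cor(E[i, ], B[i, ], method = "spearman")
  }, 0)
  stats::setNames(rho, rownames(B))
}

#' Filter correlations against a permutation null range
#'
#' The null interval is the pooled `[min, max]` of the correlations
#' obtained from the randomised (shuffled-expression) model; a TF is kept
#' only when its real correlation falls strictly outside that range.
#'
#' @param rho_real Named per-TF correlations from an actual model.
#' @param rho_null Per-TF correlations from the randomised model.
#' @return Character vector of kept TF ids, with the interval attached as
#'   attribute `null_interval`.
#' @export
permutation_null_filter <- function(rho_real, rho_null) {
  rho_null <- rho_null[!is.na(rho_null)]
  if (length(rho_null) == 0L) stop("empty null correlation set")
  lo <- min(rho_null); hi <- max(rho_null)
  kept <- names(rho_real)[!is.na(rho_real) &
                            (rho_real < lo | rho_real > hi)]
  attr(kept, "null_interval") <- c(lo, hi)
  kept
}

#' Sign-consistency filter
#'
#' Keeps a TF only when the sign of its expression-activity correlation
#' agrees with the sign of its summed coefficients, i.e.
#' `sign(rho_i) * sign(sum_j B^j_i) > 0`; a zero on either side discards
#' the TF.
#'
#' @param rho Named per-TF correlations (e.g. from [tf_expr_cor()]).
#' @param coef_sums Named per-TF sums of coefficients across cells.
#' @return Character vector of kept TF ids.
#' @export
sign_agreement_filter <- function(rho, coef_sums) {
  common <- intersect(names(rho), names(coef_sums))
  if (length(common) == 0L) stop("no shared TF ids")
  keep <- !is.na(rho[common]) &
    sign(rho[common]) * sign(coef_sums[common]) > 0
  common[keep]
}

#' Assemble the per-TF activity report
#'
#' Combines heat-map selection, activity ranking, differential activity,
#' expression-activity correlation, the permutation-null filter and the
#' sign filter into one table.
#'
#' @param fit A `tg_fit` (its `B` is used).
#' @param cell_labels Optional two-level cell-type labels for the
#'   differential test.
#' @param tf_expression Optional log2 TPM matrix for [tf_expr_cor()].
#' @param rho_null Optional null correlations for
#'   [permutation_null_filter()].
#' @param heatmap_threshold Passed to [select_heatmap_tfs()].
#' @param scaling Passed to [rank_tf_activity()].
#' @param sig_level Passed to [differential_activity()].
#' @return Data frame, one row per TF.
#' @export
activity_report <- function(fit, cell_labels = NULL, tf_expression = NULL,
                            rho_null = NULL, heatmap_threshold = 0.5,
                            scaling = "maxabs", sig_level = 0.1) {
  stopifnot(inherits(fit, "tg_fit"))
  B <- fit$B
  rk <- rank_tf_activity(B, scaling = scaling)
  out <- data.frame(tf = rownames(B),
                    summed_abs_coef = rowSums(abs(B)),
                    coef_sum = rowSums(B),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$activity <- rk$activity[match(out$tf, rk$tf)]
  out$activity_rank <- rk$rank[match(out$tf, rk$tf)]
  out$heatmap_selected <- out$tf %in%
    select_heatmap_tfs(B, heatmap_threshold)
  out$in_top20 <- out$tf %in% utils::head(rk$tf, 20L)
  if (!is.null(cell_labels)) {
    g <- table(as.character(cell_labels))
    if (length(g) != 2L || any(g < 2L)) {
      message("skipping differential activity: need two cell types with ",
              ">= 2 cells each")
      cell_labels <- NULL
    }
  }
  if (!is.null(cell_labels)) {
    da <- differential_activity(B, cell_labels, sig_level = sig_level)
    out$diff_p_raw <- da$p_raw[match(out$tf, da$tf)]
    out$diff_p_adj <- da$p_adj[match(out$tf, da$tf)]
    out$diff_significant <- da$significant[match(out$tf, da$tf)]
  }
  if (!is.null(tf_expression)) {
    rho <- tf_expr_cor(B, tf_expression)
    out$tf_expr_cor <- rho[out$tf]
    sums <- stats::setNames(out$coef_sum, out$tf)
    out$sign_agrees <- out$tf %in% sign_agreement_filter(rho, sums)
    if (!is.null(rho_null)) {
      kept <- permutation_null_filter(rho, rho_null)
      out$outside_null <- out$tf %in% kept
    }
  }
  out
}
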