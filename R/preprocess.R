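#' Gene x cell expression matrix
#'
#' @param values Numeric genes x cells matrix (nonnegative on the TPM
#'   scale) with unique dimnames.
#' @param scale_flag `"tpm"` for raw transcripts-per-million, `"log2"`
#'   after [log2_transform()].
#' @param cell_labels Optional named character/factor vector mapping every
#'   cell id to a cell type.
#' @return An `ExpressionMatrix` object.
#' @export
new_expression_matrix <- function(values, scale_flag = c("tpm", "log2"),
                                  cell_labels = NULL) {
  scale_flag <- match.arg(scale_flag)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("ExpressionMatrix needs gene and cell ids as dimnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate gene or cell ids")
  if (scale_flag == "tpm" && any(values < 0))
    stop("negative entries on the TPM scale")
  if (!is.null(cell_labels)) {
    if (!all(colnames(values) %in% names(cell_labels)))
      stop("cell_labels must cover every cell")
    cell_labels <- cell_labels[colnames(values)]
  }
  structure(list(values = values, scale_flag = scale_flag,
                 cell_labels = cell_labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d genes x %d cells (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale_flag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Detected-gene filter
#'
#' A gene is detected in a cell when its raw TPM is at least `min_expr`;
#' the gene is kept when it is detected in at least `min_cells` cells.
#' Must be applied on the TPM scale, before any log transform.
#'
#' @param expr An `ExpressionMatrix` on the `"tpm"` scale.
#' @param min_expr Detection threshold; default 0.1 TPM.
#' @param min_cells Minimum number of detecting cells; default 10.
#' @return List with `kept_genes`, `detected_counts`, `min_expr`,
#'   `min_cells`.
#' @export
detect_gene_filter <- function(expr, min_expr = 0.1, min_cells = 10L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale_flag != "tpm")
    stop("detect_gene_filter expects raw TPM values")
  if (ncol(expr$values) < min_cells)
    warning("fewer cells than min_cells; every gene may be dropped")
  detected <- rowSums(expr$values >= min_expr)
  kept <- rownames(expr$values)[detected >= min_cells]
  list(kept_genes = kept, detected_counts = detected,
       min_expr = min_expr, min_cells = min_cells)
}

#' Feature-variance filter
#'
#' Computes the sample variance of each gene's TF-affinity row and keeps
#' genes whose variance is at least the third quartile of all row
#' variances (type-7 linear-interpolation quantile). On a constant matrix
#' all variances and the threshold are zero, so everything is kept.
#'
#' @param fm A `FeatureMatrix`.
#' @return List with `kept_genes`, `per_gene_variance`, `threshold`.
#' @export
variance_filter <- function(fm) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  v <- fm$values
  if (nrow(v) < 4L) stop("variance filter needs at least 4 genes")
  vars <- apply(v, 1L, stats::var)
  t <- stats::quantile(vars, 0.75, names = FALSE, type = 7)
  kept <- rownames(v)[vars >= t]
  if (t == 0)
    message("all row variances below or at zero; keeping every gene")
  list(kept_genes = kept, per_gene_variance = vars, threshold = t)
}

#' Remove TFs whose encoding gene is never expressed
#'
#' A TF feature column is removed when the total expression of its
#' encoding gene across all cells is zero. The `Peak_Counts`,
#' `Peak_Length` and `Peak_Signal` columns of dynamic features are exempt.
#' TFs without a mapped gene are retained with a warning.
#'
#' @param fm A `FeatureMatrix`.
#' @param expr An `ExpressionMatrix`.
#' @param tf_gene_map Named character vector mapping feature ids to gene
#'   ids. Defaults to the identity map (TF name == gene name).
#' @return The reduced `FeatureMatrix`.
#' @export
drop_zero_expression_tfs <- function(fm, expr, tf_gene_map = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"),
            inherits(expr, "ExpressionMatrix"))
  feats <- colnames(fm$values)
  exempt <- feats %in% c("Peak_Counts", "Peak_Length", "Peak_Signal")
  if (is.null(tf_gene_map)) tf_gene_map <- stats::setNames(feats, feats)
  totals <- rowSums(expr$values)
  keep <- rep(TRUE, length(feats))
  unmapped <- character(0)
  for (i in which(!exempt)) {
    gene <- unname(tf_gene_map[feats[i]])
    if (is.na(gene) || !(gene %in% names(totals))) {
      unmapped <- c(unmapped, feats[i])
      next
    }
    if (totals[gene] == 0) keep[i] <- FALSE
  }
  if (length(unmapped))
    warning("retaining ", length(unmapped),
            " TF(s) without a mapped expression gene")
  new_feature_matrix(fm$values[, keep, drop = FALSE], fm$flavour)
}

#' Log2 transform with pseudocount
#'
#' `x -> log2(x + pseudocount)`; with the default pseudocount of 1 this is
#' monotone and maps 0 to 0. Applied to both feature and response matrices
#' before model fitting.
#'
#' @param x Numeric matrix, `FeatureMatrix` or `ExpressionMatrix` with
#'   nonnegative entries.
#' @param pseudocount Nonnegative offset; default 1.
#' @return Object of the same class, transformed (`scale_flag` becomes
#'   `"log2"` for expression input).
#' @export
log2_transform <- function(x, pseudocount = 1) {
  tr <- function(m) {
    if (any(m < 0)) stop("log2_transform requires nonnegative entries")
    log2(m + pseudocount)
  }
  if (inherits(x, "FeatureMatrix"))
    return(new_feature_matrix(tr(x$values), x$flavour))
  if (inherits(x, "ExpressionMatrix")) {
    out <- x
    out$values <- tr(x$values)
    out$scale_flag <- "log2"
    return(out)
  }
  tr(as.matrix(x))
}

#' Column standardisation fitted on training rows
#'
#' Centres and scales every column of `X` and `Y` to zero mean and unit
#' sample variance computed on the training rows only; test rows are
#' transformed with the training statistics. Zero-variance columns are
#' dropped with a warning.
#'
#' @param X,Y Numeric matrices sharing row order (genes).
#' @param train_idx Integer indices of the training rows; default all rows.
#' @return List with standardized `X`, `Y`, the centre/scale vectors,
#'   dropped column names and `train_idx`.
#' @export
standardize <- function(X, Y, train_idx = seq_len(nrow(X))) {
  stopifnot(nrow(X) == nrow(Y))
  fit1 <- function(M, what) {
    mu <- colMeans(M[train_idx, , drop = FALSE])
    sdv <- apply(M[train_idx, , drop = FALSE], 2L, stats::sd)
    drop <- sdv == 0 | !is.finite(sdv)
    if (any(drop))
      warning("dropping ", sum(drop), " zero-variance ", what, " column(s): ",
              paste(utils::head(colnames(M)[drop], 5L), collapse = ", "))
    keep <- !drop
    Ms <- sweep(sweep(M[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                sdv[keep], "/")
    list(M = Ms, center = mu[keep], scale = sdv[keep],
         dropped = colnames(M)[drop])
  }
  sx <- fit1(X, "feature")
  sy <- fit1(Y, "response")
  structure(list(X = sx$M, Y = sy$M,
                 x_center = sx$center, x_scale = sx$scale,
                 y_center = sy$center, y_scale = sy$scale,
                 x_dropped = sx$dropped, y_dropped = sy$dropped,
                 train_idx = train_idx),
            class = "standardization")
}

#' Apply a fitted standardisation to new feature rows
#'
#' @param st A [standardize()] result.
#' @param X_new Matrix whose columns include every retained feature.
#' @return Standardized matrix with columns in training order.
#' @export
standardize_apply <- function(st, X_new) {
  stopifnot(inherits(st, "standardization"))
  need <- names(st$x_center)
  if (!all(need %in% colnames(X_new)))
    stop("X_new lacks feature column(s): ",
         paste(utils::head(setdiff(need, colnames(X_new)), 5L),
               collapse = ", "))
  sweep(sweep(X_new[, need, drop = FALSE], 2L, st$x_center), 2L,
        st$x_scale, "/")
}

#' Map standardized predictions back to the response scale
#'
#' @param st A [standardize()] result.
#' @param Y_std Matrix on the standardized response scale.
#' @return Matrix on the original response scale.
#' @export
destandardize_response <- function(st, Y_std) {
  stopifnot(inherits(st, "standardization"),
            ncol(Y_std) == length(st$y_center))
  sweep(sweep(Y_std, 2L, st$y_scale, "*"), 2L, st$y_center, "+")
}

#' Random train/test split over genes
#'
#' Genes (rows/observations) are split uniformly at random into a training
#' fraction and its complement; cells are never split because they are the
#' regression tasks.
#'
#' @param n Number of genes (>= 5).
#' @param frac Training fraction in (0, 1); default 0.6.
#' @param seed Integer seed; recorded in the result.
#' @return List with `train`, `test` (disjoint sorted index vectors,
#'   `length(train) == round(frac * n)`), `frac` and `seed`.
#' @export
split_train_test <- function(n, frac = 0.6, seed = 1L) {
  if (n < 5L) stop("need at least 5 genes to split")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  n_train <- round(frac * n)
  train <- sort(withr::with_seed(seed, sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train),
       frac = frac, seed = seed)
}
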