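#' Default lambda grid for tree-guided cross-validation
#'
#' 21 values spanning \[0, 1\] at step 0.05.
#'
#' @return Numeric vector of length 21.
#' @export
default_lambda_grid <- function() seq(0, 1, by = 0.05)

.tree_groups <- function(tree, cell_ids = NULL) {
  stopifnot(inherits(tree, "TaskTree"))
  if (is.null(tree$groups))
    stop("tree has no groups; call compute_groups_and_weights()")
  groups <- tree$groups
  if (!is.null(cell_ids)) {
    if (!setequal(cell_ids, tree$cell_ids))
      stop("response cells and tree leaves differ")
    remap <- match(tree$cell_ids, cell_ids)
    groups <- lapply(groups, function(g) sort(remap[g]))
  }
  list(groups = groups, weights = tree$weights, order = tree$prox_order)
}

.check_laminar <- function(groups) {
  m <- length(groups)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    ga <- groups[[a]]; gb <- groups[[b]]
    inter <- length(intersect(ga, gb))
    if (inter > 0L && inter < min(length(ga), length(gb)))
      stop("groups are not laminar")
    if (inter > 0L && !(all(ga %in% gb) || all(gb %in% ga)))
      stop("groups are not laminar")
  }
  invisible(TRUE)
}

#' Tree-guided group-lasso objective
#'
#' `sum_i ||y_i - X b_i||^2 + lambda * sum_j sum_v w_v ||b^j_{G_v}||_2`,
#' i.e. an un-halved residual sum of squares plus, for every feature row
#' `j` and tree node `v`, the weighted L2 norm of the coefficients of the
#' tasks grouped under `v`.
#'
#' @param X n x p standardized feature matrix.
#' @param Y n x k standardized response matrix.
#' @param B p x k coefficient matrix.
#' @param tree A `TaskTree` with groups and weights.
#' @param lam Penalty parameter `lambda >= 0`.
#' @return Nonnegative scalar.
#' @export
tree_objective <- function(X, Y, B, tree, lam) {
  if (nrow(X) != nrow(Y) || ncol(X) != nrow(B) || ncol(Y) != ncol(B))
    stop("dimension mismatch between X, Y and B")
  tg <- .tree_groups(tree, colnames(Y))
  rss <- sum((Y - X %*% B)^2)
  pen <- 0
  for (v in seq_along(tg$groups)) {
    sub <- B[, tg$groups[[v]], drop = FALSE]
    pen <- pen + tg$weights[v] * sum(sqrt(rowSums(sub * sub)))
  }
  rss + lam * pen
}

# Exact proximal operator of tau * sum_v w_v ||.||_2 over a laminar group
# family: one pass of group soft-thresholding ordered leaves-to-root.
.prox_tree <- function(B, tau, groups, weights, ord) {
  for (v in ord) {
    g <- groups[[v]]
    sub <- B[, g, drop = FALSE]
    nr <- sqrt(rowSums(sub * sub))
    shrink <- pmax(0, 1 - (tau * weights[v]) / nr)
    shrink[nr == 0] <- 0
    B[, g] <- sub * shrink
  }
  B
}

.penalty_value <- function(B, groups, weights) {
  pen <- 0
  for (v in seq_along(groups)) {
    sub <- B[, groups[[v]], drop = FALSE]
    pen <- pen + weights[v] * sum(sqrt(rowSums(sub * sub)))
  }
  pen
}

# Accelerated proximal gradient (FISTA) with monotone safeguard: whenever
# the momentum step would raise the objective, the iteration falls back to
# a plain proximal-gradient step from the last accepted iterate, which can
# never increase the objective at step size 1/L.
.fista <- function(X, Y, lam, groups, weights, ord, max_iter, tol,
                   B_init = NULL, ridge = 0) {
  p <- ncol(X); k <- ncol(Y)
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values) + 2 * ridge
  if (L <= 0) L <- 1
  obj <- function(B)
    sum((Y - X %*% B)^2) + ridge * sum(B * B) +
      lam * .penalty_value(B, groups, weights)
  grad <- function(B) 2 * crossprod(X, X %*% B - Y) + 2 * ridge * B
  B <- if (is.null(B_init)) matrix(0, p, k) else B_init
  Z <- B
  t_k <- 1
  f_prev <- obj(B)
  objective <- f_prev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cand <- .prox_tree(Z - grad(Z) / L, lam / L, groups, weights, ord)
    f_cand <- obj(cand)
    if (f_cand > f_prev + 1e-12) {
      cand <- .prox_tree(B - grad(B) / L, lam / L, groups, weights, ord)
      f_cand <- obj(cand)
      t_k <- 1
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    Z <- cand + ((t_k - 1) / t_new) * (cand - B)
    B <- cand
    t_k <- t_new
    objective <- c(objective, f_cand)
    if (abs(f_prev - f_cand) <= tol * max(1, f_prev)) {
      converged <- TRUE
      f_prev <- f_cand
      break
    }
    f_prev <- f_cand
  }
  list(B = B, objective = objective, converged = converged,
       iterations = length(objective) - 1L)
}

.new_fit <- function(B, model_kind, lambda, alpha, tree, objective,
                     converged, iterations, standardization = NULL,
                     split = NULL, cv = NULL) {
  structure(list(B = B, model_kind = model_kind, lambda = lambda,
                 alpha = alpha, tree = tree, objective = objective,
                 converged = converged, iterations = iterations,
                 standardization = standardization, split = split,
                 cv = cv),
            class = "tg_fit")
}

#' @export
print.tg_fit <- function(x, ...) {
  cat(sprintf(
    "<tg_fit> %s model: %d features x %d tasks, lambda=%g (%d iter%s)\n",
    x$model_kind, nrow(x$B), ncol(x$B), x$lambda, x$iterations,
    if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' Fit the tree-guided group-lasso multi-task model
#'
#' Minimises [tree_objective()] by accelerated proximal gradient descent
#' with an exact single-pass proximal operator for the laminar tree
#' groups. Inputs are expected to be standardized (zero-mean/unit-variance
#' columns); no intercept is fitted.
#'
#' @inheritParams tree_objective
#' @param max_iter Maximum iterations; default 1000.
#' @param tol Relative objective-change stopping tolerance; default 1e-6.
#' @param B_init Optional warm start.
#' @return A `tg_fit` with the coefficient matrix `B` (features x cells),
#'   the nonincreasing objective log, and convergence information.
#' @export
fit_tree_guided <- function(X, Y, tree, lam, max_iter = 1000L, tol = 1e-6,
                            B_init = NULL) {
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (lam < 0) stop("lambda must be nonnegative")
  tg <- .tree_groups(tree, colnames(Y))
  res <- .fista(X, Y, lam, tg$groups, tg$weights, tg$order,
                max_iter = max_iter, tol = tol, B_init = B_init)
  if (any(diff(res$objective) > 1e-12 * pmax(1, res$objective[-1])))
    stop("objective increased during optimisation; diagnostics: ",
         paste(utils::head(res$objective), collapse = " "))
  dimnames(res$B) <- list(colnames(X), colnames(Y))
  .new_fit(res$B, "tree", lam, NA_real_, tree, res$objective,
           res$converged, res$iterations)
}

#' Smallest penalty that provably zeroes all coefficients
#'
#' KKT-derived bound for [fit_tree_guided()]: since the penalty of each
#' feature row dominates `w_root * ||b^j||_2`, `B = 0` is optimal whenever
#' `lambda >= max_j 2 ||(X'Y)^j||_2 / w_root`.
#'
#' @inheritParams tree_objective
#' @return Scalar `lambda_max`.
#' @export
lambda_max_tree <- function(X, Y, tree) {
  tg <- .tree_groups(tree, colnames(Y))
  w_root <- tg$weights[which(lengths(tg$groups) == n_tasks(tree))[1L]]
  g <- 2 * crossprod(X, Y)
  max(sqrt(rowSums(g * g))) / w_root
}

#' Fit the ordinary multi-task (row group-lasso) model
#'
#' Minimises `sum_i ||y_i - X b_i||^2 + alpha * sum_j ||b^j||_2`
#' (+ optionally `ridge * ||B||_F^2`), selecting or zeroing each feature
#' row jointly across all tasks. The default is the pure group penalty;
#' the ridge term emulates the multi-response elastic-net family.
#'
#' @inheritParams fit_tree_guided
#' @param alpha Group-penalty strength `>= 0`.
#' @param ridge Optional ridge coefficient; default 0.
#' @return A `tg_fit` with `model_kind = "omtl"`.
#' @export
fit_omtl <- function(X, Y, alpha, ridge = 0, max_iter = 1000L, tol = 1e-6,
                     B_init = NULL) {
  if (alpha < 0 || ridge < 0) stop("penalties must be nonnegative")
  groups <- list(seq_len(ncol(Y)))
  res <- .fista(X, Y, alpha, groups, 1, 1L, max_iter = max_iter, tol = tol,
                B_init = B_init, ridge = ridge)
  dimnames(res$B) <- list(colnames(X), colnames(Y))
  .new_fit(res$B, "omtl", alpha, alpha, NULL, res$objective,
           res$converged, res$iterations)
}

#' Fit a single-task elastic net for one cell
#'
#' One glmnet elastic-net regression of a single cell's expression on the
#' features, with the mixing parameter explored over `alpha_grid`
#' (default 0, 0.1, ..., 1) and `lambda` chosen by cross-validation at
#' each `alpha` (shared fold assignment).
#'
#' @param X n x p standardized feature matrix.
#' @param y Length-n response vector for one cell.
#' @param alpha_grid Mixing grid; default `seq(0, 1, by = 0.1)`.
#' @param folds Number of CV folds; default 5.
#' @param seed Seed for the fold assignment.
#' @return A `tg_fit` with a one-column `B` (`model_kind = "stl"`); the
#'   chosen `alpha` and `lambda` are recorded.
#' @export
fit_stl <- function(X, y, alpha_grid = seq(0, 1, by = 0.1), folds = 5L,
                    seed = 1L) {
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) {
    warning("constant response; returning null model")
    B <- matrix(0, ncol(X), 1L, dimnames = list(colnames(X), NULL))
    return(.new_fit(B, "stl", NA_real_, NA_real_, NULL, NA_real_, TRUE, 0L))
  }
  foldid <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = nrow(X))))
  best <- NULL
  for (a in alpha_grid) {
    cvf <- glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid,
                             standardize = FALSE)
    loss <- min(cvf$cvm)
    if (is.null(best) || loss < best$loss)
      best <- list(loss = loss, alpha = a, lambda = cvf$lambda.min,
                   fit = cvf)
  }
  co <- as.matrix(stats::coef(best$fit, s = "lambda.min"))[-1L, , drop = FALSE]
  rownames(co) <- colnames(X)
  .new_fit(co, "stl", best$lambda, best$alpha, NULL, best$loss, TRUE, 0L)
}

#' Cross-validate the tree-guided penalty parameter
#'
#' Gene-wise k-fold cross-validation of [fit_tree_guided()] over a lambda
#' grid (default: 21 values spanning \[0, 1\] at step 0.05); the selected
#' value minimises the mean validation squared error pooled over tasks,
#' with ties broken towards the smaller lambda.
#'
#' @inheritParams fit_tree_guided
#' @param lambda_grid Candidate values; default [default_lambda_grid()].
#' @param folds Number of folds; default 5.
#' @param seed Seed for the fold assignment.
#' @return A `CvResult` list: `lambda_grid`, `mean_loss`, `fold_loss`
#'   (folds x grid), `selected`, `foldid`, `seed`.
#' @export
cross_validate_tree <- function(X, Y, tree,
                                lambda_grid = default_lambda_grid(),
                                folds = 5L, seed = 1L, max_iter = 1000L,
                                tol = 1e-6) {
  if (length(lambda_grid) == 0L) stop("empty lambda grid")
  n <- nrow(X)
  if (n < folds) stop("fewer training genes than folds")
  lambda_grid <- sort(lambda_grid)
  foldid <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = n)))
  fold_loss <- matrix(NA_real_, folds, length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    B0 <- NULL
    for (li in seq_along(lambda_grid)) {
      fit <- fit_tree_guided(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                             tree, lambda_grid[li], max_iter = max_iter,
                             tol = tol, B_init = B0)
      B0 <- fit$B
      resid <- Y[!tr, , drop = FALSE] - X[!tr, , drop = FALSE] %*% fit$B
      fold_loss[f, li] <- mean(resid^2)
    }
  }
  mean_loss <- colMeans(fold_loss)
  sel <- lambda_grid[which.min(mean_loss)]
  structure(list(lambda_grid = lambda_grid, mean_loss = mean_loss,
                 fold_loss = fold_loss, selected = sel, foldid = foldid,
                 seed = seed),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("<CvResult> %d lambdas, selected %g (mean loss %.4g)\n",
              length(x$lambda_grid), x$selected, min(x$mean_loss)))
  invisible(x)
}

#' Predict expression for new genes
#'
#' If the fit carries a standardisation state the new features are
#' standardized with the stored training statistics and predictions are
#' mapped back to the response scale; otherwise `X_new %*% B` is returned
#' on the (standardized) training scale.
#'
#' @param object A `tg_fit`.
#' @param X_new Feature matrix whose columns cover the training features.
#' @param ... Unused.
#' @return Predicted response matrix.
#' @export
predict.tg_fit <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (!is.null(object$standardization)) {
    Xs <- standardize_apply(object$standardization, X_new)
    return(destandardize_response(object$standardization, Xs %*% object$B))
  }
  if (!is.null(rownames(object$B))) {
    if (!all(rownames(object$B) %in% colnames(X_new)))
      stop("X_new lacks feature column(s) seen in training")
    X_new <- X_new[, rownames(object$B), drop = FALSE]
  } else if (ncol(X_new) != nrow(object$B)) {
    stop("X_new has ", ncol(X_new), " columns; fit expects ",
         nrow(object$B))
  }
  X_new %*% object$B
}

#' Per-cell Pearson correlation between prediction and truth
#'
#' One correlation per cell (task) computed across test genes. A cell with
#' a constant prediction or constant truth has an undefined correlation
#' and is recorded as `NA` (never coerced to 0); the count of such cells
#' is attached as attribute `n_missing`.
#'
#' @param Y_hat,Y_test Matrices of identical shape with >= 3 rows.
#' @return Named numeric vector of per-cell correlations.
#' @export
evaluate_per_cell <- function(Y_hat, Y_test) {
  Y_hat <- as.matrix(Y_hat); Y_test <- as.matrix(Y_test)
  if (!all(dim(Y_hat) == dim(Y_test))) stop("shape mismatch")
  if (nrow(Y_test) < 3L) stop("need at least 3 test genes")
  r <- vapply(seq_len(ncol(Y_test)), function(j) {
    if (stats::sd(Y_hat[, j]) == 0 || stats::sd(Y_test[, j]) == 0)
      return(NA_real_)
    stats::cor(Y_hat[, j], Y_test[, j])
  }, 0)
  names(r) <- colnames(Y_test)
  attr(r, "n_missing") <- sum(is.na(r))
  r
}
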