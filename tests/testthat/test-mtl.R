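test_that("default lambda grid is 0..1 at step 0.05", {
  g <- default_lambda_grid()
  expect_length(g, 21L)
  expect_equal(range(g), c(0, 1))
  expect_equal(unique(round(diff(g), 10)), 0.05)
})

test_that("tree_objective matches the naive double-loop oracle", {
  withr::with_seed(31, {
    inst <- random_instance(20, 5, 4, seed = 31)
    tr <- random_task_tree(4, seed = 31)
    B <- matrix(rnorm(5 * 4), 5, 4)
    expect_equal(tree_objective(inst$X, inst$Y, B, tr, 0.3),
                 oracle_tree_objective(inst$X, inst$Y, B, tr$groups,
                                       tr$weights, 0.3),
                 tolerance = 1e-10)
    # degenerate anchors
    expect_equal(tree_objective(inst$X, inst$Y, B * 0, tr, 0.3),
                 sum(inst$Y^2), tolerance = 1e-10)
    expect_equal(tree_objective(inst$X, inst$Y, B, tr, 0),
                 sum((inst$Y - inst$X %*% B)^2), tolerance = 1e-10)
    expect_error(tree_objective(inst$X, inst$Y, B[1:3, ], tr, 0.3),
                 "dimension")
  })
})

test_that("lambda=0 fit reproduces per-task least squares", {
  inst <- random_instance(40, 5, 3, seed = 32)
  tr <- random_task_tree(3, seed = 32)
  fit <- fit_tree_guided(inst$X, inst$Y, tr, 0, max_iter = 20000,
                         tol = 1e-14)
  ols <- qr.solve(inst$X, inst$Y)
  expect_lt(max(abs(fit$B - ols)), 1e-6)
  # residuals orthogonal to the design, per normal equations
  expect_lt(max(abs(crossprod(inst$X, inst$Y - inst$X %*% fit$B))), 1e-4)
})

test_that("lambda above the KKT bound zeroes every coefficient", {
  inst <- random_instance(30, 6, 4, seed = 33)
  tr <- random_task_tree(4, seed = 33)
  lmax <- lambda_max_tree(inst$X, inst$Y, tr)
  fit <- fit_tree_guided(inst$X, inst$Y, tr, lmax * 1.001)
  expect_equal(unname(fit$B), matrix(0, 6, 4))
})

test_that("objective log is nonincreasing and fit converges", {
  inst <- random_instance(30, 6, 4, seed = 34)
  tr <- random_task_tree(4, seed = 34)
  fit <- fit_tree_guided(inst$X, inst$Y, tr, 0.2)
  expect_true(all(diff(fit$objective) <= 1e-12 *
                    pmax(1, fit$objective[-1])))
  expect_true(fit$converged)
})

test_that("tree solver reaches the convex oracle objective", {
  for (seed in 1:6) {
    inst <- random_instance(30, 6, 4, seed = seed)
    tr <- random_task_tree(4, seed = seed)
    lam <- c(0.05, 0.2, 0.5, 1, 2, 5)[seed]
    fit <- fit_tree_guided(inst$X, inst$Y, tr, lam, max_iter = 5000,
                           tol = 1e-12)
    ours <- tree_objective(inst$X, inst$Y, fit$B, tr, lam)
    orac <- oracle_convex_solve(inst$X, inst$Y, tr$groups, tr$weights, lam)
    expect_lt(abs(ours - orac) / abs(orac), 1e-4)
  }
})

test_that("star tree with declared weights equals a sparse-group penalty", {
  inst <- random_instance(25, 5, 3, seed = 36)
  star <- build_star_tree(colnames(inst$Y))
  lam <- 0.8
  fit <- fit_tree_guided(inst$X, inst$Y, star, lam, max_iter = 5000,
                         tol = 1e-12)
  # sparse group lasso: w_root * ||row||_2 + sum_i w_i |b_i| per row
  groups <- c(list(1:3), as.list(1:3))
  weights <- c(2, 1, 1, 1)
  orac <- oracle_convex_solve(inst$X, inst$Y, groups, weights, lam)
  ours <- tree_objective(inst$X, inst$Y, fit$B, star, lam)
  expect_lt(abs(ours - orac) / abs(orac), 1e-4)
})

test_that("omtl solver matches oracle and zeroes rows jointly", {
  for (seed in 1:3) {
    inst <- random_instance(30, 6, 4, seed = 40 + seed)
    alpha <- c(0.5, 2, 8)[seed]
    fit <- fit_omtl(inst$X, inst$Y, alpha, max_iter = 5000, tol = 1e-12)
    ours <- sum((inst$Y - inst$X %*% fit$B)^2) +
      alpha * sum(sqrt(rowSums(fit$B^2)))
    orac <- oracle_convex_solve(inst$X, inst$Y, list(1:4), 1, alpha)
    expect_lt(abs(ours - orac) / abs(orac), 1e-4)
    # row support is joint across tasks
    nz <- rowSums(fit$B != 0)
    expect_true(all(nz == 0 | nz == 4))
  }
  # huge penalty kills everything
  inst <- random_instance(30, 6, 4, seed = 44)
  fit0 <- fit_omtl(inst$X, inst$Y, 1e5)
  expect_equal(unname(fit0$B), matrix(0, 6, 4))
})

test_that("single-task elastic net recovers a planted sparse signal", {
  withr::with_seed(50, {
    X <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
    beta <- c(2, -1.5, rep(0, 8))
    y <- X %*% beta
  })
  fit <- fit_stl(X, y, seed = 3)
  expect_equal(fit$model_kind, "stl")
  expect_lt(max(abs(fit$B[, 1] - beta)), 1e-1)
  expect_equal(which(abs(fit$B[, 1]) > 0.5), c(f01 = 1L, f02 = 2L))
  expect_warning(fit0 <- fit_stl(X, rep(1, 200)), "constant")
  expect_equal(unname(fit0$B), matrix(0, 10, 1))
})

test_that("cross-validation selects the arg-min and is reproducible", {
  fx <- generate_regression_fixture(n = 120, p = 10, k = 8,
                                    n_clusters = 2, tfs_per_cluster = 2,
                                    seed = 5)
  st <- standardize(fx$X$values, fx$Y$values)
  tr <- fx$tree
  cv <- cross_validate_tree(st$X, st$Y, tr,
                            lambda_grid = c(0, 0.1, 0.4, 1), folds = 3,
                            seed = 11, max_iter = 300)
  expect_equal(cv$selected,
               cv$lambda_grid[which.min(cv$mean_loss)])
  expect_true(all(cv$mean_loss[cv$lambda_grid == cv$selected] <=
                    cv$mean_loss))
  cv2 <- cross_validate_tree(st$X, st$Y, tr,
                             lambda_grid = c(0, 0.1, 0.4, 1), folds = 3,
                             seed = 11, max_iter = 300)
  expect_equal(cv$mean_loss, cv2$mean_loss)
  expect_error(cross_validate_tree(st$X, st$Y, tr, numeric(0)), "empty")
})

test_that("optimal objective is nondecreasing in lambda", {
  inst <- random_instance(30, 6, 4, seed = 60)
  tr <- random_task_tree(4, seed = 60)
  grid <- c(0, 0.05, 0.2, 0.5, 1, 2)
  vals <- vapply(grid, function(l)
    tree_objective(inst$X, inst$Y,
                   fit_tree_guided(inst$X, inst$Y, tr, l,
                                   max_iter = 5000, tol = 1e-12)$B,
                   tr, l), 0)
  expect_true(all(diff(vals) >= -1e-8))
})

test_that("predict maps through standardisation and checks columns", {
  fx <- generate_regression_fixture(n = 80, p = 6, k = 4, n_clusters = 2,
                                    tfs_per_cluster = 1, seed = 6)
  st <- standardize(fx$X$values, fx$Y$values, 1:48)
  fit <- fit_tree_guided(st$X[1:48, ], st$Y[1:48, ], fx$tree, 0.05)
  fit$standardization <- st
  pred <- predict(fit, fx$X$values[49:80, ])
  expect_equal(dim(pred), c(32L, ncol(st$Y)))
  expect_error(predict(fit, fx$X$values[, 1:3]), "lacks feature")
  # zero standardized input predicts the training column means
  fit2 <- fit_tree_guided(st$X, st$Y, fx$tree, 0.05)
  z <- matrix(0, 2, ncol(st$X), dimnames = list(NULL, colnames(st$X)))
  expect_equal(unname(z %*% fit2$B), matrix(0, 2, ncol(st$Y)))
})

test_that("evaluate_per_cell anchors and missing handling", {
  withr::with_seed(70, {
    Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  expect_equal(unname(evaluate_per_cell(Y, Y)), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(unname(evaluate_per_cell(-Y, Y)), rep(-1, 3),
               ignore_attr = TRUE)
  Yc <- Y; Yc[, 2] <- 5
  r <- evaluate_per_cell(Yc, Y)
  expect_true(is.na(r["b"]))
  expect_equal(attr(r, "n_missing"), 1L)
  expect_error(evaluate_per_cell(Y[1:2, ], Y[1:2, ]), "3 test genes")
  # independent noise: mean r near 0
  withr::with_seed(71, {
    A <- matrix(rnorm(2000), 100, 20)
    B <- matrix(rnorm(2000), 100, 20)
  })
  colnames(A) <- colnames(B) <- sprintf("c%02d", 1:20)
  expect_lt(abs(mean(evaluate_per_cell(A, B))), 0.08)
})
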