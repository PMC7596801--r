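# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (loops, enumeration, smoothing) sharing no code with the
# package internals it checks.

# --- TRAP affinity: explicit per-window evaluation on both strands -------
oracle_trap <- function(sequence, pwm, lambda_trap = 0.7, ln_r0 = NULL) {
  L <- pwm$length
  if (is.null(ln_r0)) ln_r0 <- 0.584 * L - 5.66
  one_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    total <- 0
    if (length(chars) < L) return(0)
    for (i in 1:(length(chars) - L + 1)) {
      win <- chars[i:(i + L - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      e <- 0
      for (j in seq_len(L)) {
        col <- pwm$prob[, j]
        e <- e + log(max(col)) - log(col[win[j]])
      }
      total <- total + 1 / (1 + exp(unname(e) / lambda_trap - ln_r0))
    }
    total
  }
  rc <- paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(sequence, "")[[1]])), collapse = "")
  one_strand(toupper(sequence)) + one_strand(toupper(rc))
}

# --- brute-force half-open interval overlap ------------------------------
oracle_overlaps <- function(ws, we, ps, pe) {
  # returns logical matrix [window, peak]
  outer(seq_along(ws), seq_along(ps), Vectorize(function(i, j)
    ps[j] < we[i] && pe[j] > ws[i]))
}

# --- naive double-loop objective of the tree-guided model ----------------
oracle_tree_objective <- function(X, Y, B, groups, weights, lam) {
  val <- 0
  for (i in seq_len(ncol(Y)))
    val <- val + sum((Y[, i] - X %*% B[, i])^2)
  for (j in seq_len(nrow(B)))
    for (v in seq_along(groups))
      val <- val + lam * sqrt(sum((weights[v] * B[j, groups[[v]]])^2))
  val
}

# --- generic convex solver: smoothed penalty + BFGS continuation ---------
oracle_convex_solve <- function(X, Y, groups, weights, lam, ridge = 0,
                                mus = c(1e-2, 1e-4, 1e-6)) {
  p <- ncol(X); k <- ncol(Y)
  fobj <- function(b, mu) {
    B <- matrix(b, p, k)
    val <- sum((Y - X %*% B)^2) + ridge * sum(B^2)
    for (v in seq_along(groups)) {
      sub <- B[, groups[[v]], drop = FALSE]
      val <- val + lam * weights[v] * sum(sqrt(rowSums(sub^2) + mu^2))
    }
    val
  }
  fgrad <- function(b, mu) {
    B <- matrix(b, p, k)
    G <- -2 * crossprod(X, Y - X %*% B) + 2 * ridge * B
    for (v in seq_along(groups)) {
      g <- groups[[v]]
      sub <- B[, g, drop = FALSE]
      G[, g] <- G[, g] + lam * weights[v] * sub /
        sqrt(rowSums(sub^2) + mu^2)
    }
    as.numeric(G)
  }
  b <- numeric(p * k)
  for (mu in mus)
    b <- stats::optim(b, fobj, fgrad, mu = mu, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))$par
  B <- matrix(b, p, k)
  oracle_tree_objective(X, Y, B, groups, weights, lam) +
    ridge * sum(B^2)
}

# --- naive complete-linkage agglomeration --------------------------------
# Returns the list of clusters (sorted index vectors) created by merges.
oracle_complete_linkage <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    m <- length(clusters)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    newc <- sort(c(clusters[[bi]], clusters[[bj]]))
    merges[[length(merges) + 1]] <- newc
    clusters[[bi]] <- newc
    clusters[[bj]] <- NULL
  }
  merges
}

# --- exact two-sided Mann-Whitney by full enumeration --------------------
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  u_of <- function(idx) {
    r <- rank(comb)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, function(idx) {
    r <- rank(comb)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# --- Benjamini-Hochberg step-up from scratch -----------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- tied-rank Spearman: average ranks then Pearson ----------------------
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# --- random binary task tree over k tasks --------------------------------
random_task_tree <- function(k, seed = 1) {
  withr::with_seed(seed, {
    parent <- rep(NA_integer_, 2 * k - 1)
    avail <- seq_len(k)
    nxt <- k + 1L
    while (length(avail) > 1) {
      pick <- sample(length(avail), 2)
      parent[avail[pick]] <- nxt
      avail <- c(avail[-pick], nxt)
      nxt <- nxt + 1L
    }
    compute_groups_and_weights(
      new_task_tree(parent, sprintf("c%02d", seq_len(k)), seq_len(k)))
  })
}

# small standardized random regression instance
random_instance <- function(n, p, k, seed = 1) {
  withr::with_seed(seed, {
    X <- scale(matrix(rnorm(n * p), n, p))
    Y <- scale(matrix(rnorm(n * k), n, k))
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
    colnames(X) <- sprintf("f%02d", seq_len(p))
    colnames(Y) <- sprintf("c%02d", seq_len(k))
    list(X = X, Y = Y)
  })
}
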