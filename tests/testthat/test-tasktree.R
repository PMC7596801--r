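group_signatures <- function(tree) {
  sort(vapply(tree$groups, function(g)
    paste(sort(tree$cell_ids[g]), collapse = ","), ""))
}

test_that("star tree has k+1 nodes, unit-depth leaves and weights 1/2", {
  tr <- build_star_tree(c("a", "b", "c"))
  expect_equal(tr$n_nodes, 4L)
  expect_equal(length(tr$children[[tr$root]]), 3L)
  expect_true(all(tr$parent[-tr$root] == tr$root))
  expect_equal(sort(tr$weights), c(1, 1, 1, 2))
  expect_equal(sort(tr$groups[[tr$root]]), 1:3)
  tr1 <- build_star_tree("solo")
  expect_equal(tr1$n_nodes, 2L)
  expect_error(build_star_tree(character(0)), "empty")
})

test_that("groups and weights follow the subtree-height rule", {
  # balanced binary tree over 4 leaves: internals weight 2, root 3
  # nodes: 1 root, 2-3 internal, 4-7 leaves
  parent <- c(NA, 1L, 1L, 2L, 2L, 3L, 3L)
  tr <- compute_groups_and_weights(
    new_task_tree(parent, c("w", "x", "y", "z"), 4:7))
  expect_equal(tr$weights, c(3, 2, 2, 1, 1, 1, 1))
  expect_equal(tr$groups[[1]], 1:4)
  expect_equal(tr$groups[[2]], 1:2)
  # normalized variant
  trn <- compute_groups_and_weights(
    new_task_tree(parent, c("w", "x", "y", "z"), 4:7), normalize = TRUE)
  expect_equal(max(trn$weights), 1)
})

test_that("groups form a laminar family with one full-size group", {
  for (seed in 1:5) {
    tr <- random_task_tree(sample(3:9, 1), seed = seed)
    k <- n_tasks(tr)
    sizes <- lengths(tr$groups)
    expect_equal(sum(sizes == 1L), k)
    expect_equal(sum(sizes == k), 1L)
    # brute-force laminarity
    for (a in seq_along(tr$groups)) for (b in seq_along(tr$groups)) {
      ga <- tr$groups[[a]]; gb <- tr$groups[[b]]
      inter <- intersect(ga, gb)
      expect_true(length(inter) == 0 || all(ga %in% gb) || all(gb %in% ga))
    }
  }
})

test_that("new_task_tree rejects malformed structures", {
  expect_error(new_task_tree(c(2L, NA, NA), c("a"), 1L), "one root")
  expect_error(new_task_tree(c(NA, 9L), "a", 2L), "out of range")
  expect_error(new_task_tree(c(NA, 1L), c("a", "a"), c(1L, 2L)),
               "duplicated")
})

test_that("build_hc_tree splits perfectly anticorrelated groups first", {
  base <- c(1, 2, 3, 4, 5)
  m <- cbind(a1 = base, a2 = 2 * base + 1, b1 = -base, b2 = -3 * base)
  rownames(m) <- sprintf("g%d", 1:5)
  tr <- build_hc_tree(new_expression_matrix(m, "log2"))
  sig <- group_signatures(tr)
  expect_true("a1,a2" %in% sig)
  expect_true("b1,b2" %in% sig)
  # constant cell is named in the error
  m2 <- m; m2[, "b2"] <- 3
  expect_error(build_hc_tree(new_expression_matrix(m2, "log2")), "b2")
})

test_that("hc tree merges equal the naive complete-linkage oracle", {
  withr::with_seed(21, {
    m <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("c%d", 1:6)))
  })
  tr <- build_hc_tree(new_expression_matrix(m, "log2"))
  D <- as.matrix(1 - cor(m))
  merges <- oracle_complete_linkage(D)
  osig <- sort(vapply(merges, function(g)
    paste(sort(colnames(m)[g]), collapse = ","), ""))
  internal <- group_signatures(tr)
  internal <- internal[vapply(strsplit(internal, ","), length, 0L) > 1]
  expect_equal(sort(internal), osig)
})

test_that("hc tree is order invariant up to relabelling", {
  withr::with_seed(22, {
    m <- matrix(rnorm(40 * 7), 40, 7,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("c%d", 1:7)))
  })
  t1 <- build_hc_tree(new_expression_matrix(m, "log2"))
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  t2 <- build_hc_tree(new_expression_matrix(m[, perm], "log2"))
  expect_equal(group_signatures(t1), group_signatures(t2))
})

test_that("embedding tree separates distant clouds and checks input", {
  withr::with_seed(23, {
    cloud1 <- matrix(rnorm(8, sd = 0.1), 4, 2)
    cloud2 <- matrix(rnorm(8, mean = 50, sd = 0.1), 4, 2)
  })
  coords <- rbind(cloud1, cloud2)
  rownames(coords) <- sprintf("c%d", 1:8)
  tr <- build_embedding_tree(coords)
  sig <- group_signatures(tr)
  expect_true(paste(sort(sprintf("c%d", 1:4)), collapse = ",") %in% sig)
  expect_true(paste(sort(sprintf("c%d", 5:8)), collapse = ",") %in% sig)
  # permuting input rows gives an isomorphic tree
  tr2 <- build_embedding_tree(coords[sample(8), ])
  expect_equal(group_signatures(tr), group_signatures(tr2))
  dup <- coords; rownames(dup)[2] <- "c1"
  expect_error(build_embedding_tree(dup), "duplicated")
})

test_that("shuffle_expression preserves per-cell multisets, seeded", {
  withr::with_seed(30, {
    m <- matrix(rexp(50 * 5), 50, 5,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("c%d", 1:5)))
  })
  e <- new_expression_matrix(m, "tpm")
  s1 <- shuffle_expression(e, seed = 7)
  expect_equal(colSums(s1$values), colSums(m))
  expect_equal(apply(s1$values, 2, sort), apply(m, 2, sort))
  expect_identical(s1$values, shuffle_expression(e, seed = 7)$values)
  s2 <- shuffle_expression(e, seed = 8)
  expect_false(identical(s1$values, s2$values))
  expect_false(identical(s1$values, m))
})

test_that("task tree Newick round trip preserves topology and weights", {
  for (seed in c(2, 3)) {
    tr <- random_task_tree(6, seed = seed)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_task_tree(tr, path)
    back <- read_task_tree(path)
    expect_equal(group_signatures(back), group_signatures(tr))
    # weights matched through leaf-set signatures
    sig_w <- function(t) {
      s <- vapply(t$groups, function(g)
        paste(sort(t$cell_ids[g]), collapse = ","), "")
      setNames(t$weights, s)[order(s)]
    }
    expect_equal(sig_w(back), sig_w(tr))
  }
  star <- build_star_tree(c("a", "b", "c"))
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_task_tree(star, p2)
  expect_equal(group_signatures(read_task_tree(p2)),
               group_signatures(star))
})
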