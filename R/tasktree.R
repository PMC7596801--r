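#' Task tree over the cells of an expression matrix
#'
#' A rooted tree whose leaves are the cells (tasks) of a multi-task
#' regression. Each node `v` carries the group `G_v` of tasks below it and
#' a positive weight `w_v`; the groups of a rooted tree form a laminar
#' family, which is what makes the penalty's proximal operator exact.
#'
#' @param parent Integer vector, one entry per node; `NA` for the root.
#' @param cell_ids Character vector of cell ids, one per leaf, in task
#'   order.
#' @param leaf_nodes Integer vector: node id of the leaf carrying task
#'   `i`.
#' @return A `TaskTree`; call [compute_groups_and_weights()] to fill
#'   `groups` and `weights`.
#' @export
new_task_tree <- function(parent, cell_ids, leaf_nodes) {
  n <- length(parent)
  if (sum(is.na(parent)) != 1L) stop("tree must have exactly one root")
  root <- which(is.na(parent))
  if (any(stats::na.omit(parent) < 1L) || any(stats::na.omit(parent) > n))
    stop("parent pointer out of range")
  if (length(cell_ids) != length(leaf_nodes))
    stop("cell_ids and leaf_nodes lengths differ")
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids")
  # cycle check: every node must reach the root
  for (v in seq_len(n)) {
    seen <- logical(n)
    u <- v
    while (!is.na(parent[u])) {
      if (seen[u]) stop("cycle detected in tree")
      seen[u] <- TRUE
      u <- parent[u]
    }
  }
  children <- split(seq_len(n)[!is.na(parent)],
                    factor(parent[!is.na(parent)], levels = seq_len(n)))
  structure(list(parent = parent, children = children, root = root,
                 cell_ids = cell_ids, leaf_nodes = as.integer(leaf_nodes),
                 n_nodes = n, groups = NULL, weights = NULL),
            class = "TaskTree")
}

#' @export
print.TaskTree <- function(x, ...) {
  cat(sprintf("<TaskTree> %d nodes, %d leaves/tasks%s\n", x$n_nodes,
              length(x$cell_ids),
              if (is.null(x$weights)) " (groups/weights unset)" else ""))
  invisible(x)
}

#' Number of tasks (leaves) of a TaskTree
#' @param tree A `TaskTree`.
#' @return Integer.
#' @export
n_tasks <- function(tree) length(tree$cell_ids)

#' Fill node groups and weights of a task tree
#'
#' `G_v` is the set of tasks (leaves) in the subtree rooted at `v`; the
#' weight `w_v` is the height of that subtree counted in nodes (leaves have
#' height 1), optionally normalised by the root height so that the largest
#' weight is 1.
#'
#' @param tree A `TaskTree`.
#' @param normalize Divide all weights by the root weight? Default FALSE.
#' @return The tree with `groups`, `weights`, `heights` and `prox_order`
#'   (nodes sorted leaves-to-root) filled in.
#' @export
compute_groups_and_weights <- function(tree, normalize = FALSE) {
  stopifnot(inherits(tree, "TaskTree"))
  n <- tree$n_nodes
  groups <- vector("list", n)
  heights <- integer(n)
  task_of_leaf <- integer(n)
  task_of_leaf[tree$leaf_nodes] <- seq_along(tree$leaf_nodes)
  # postorder via DFS from root
  order <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(v, order)
    stack <- c(stack, tree$children[[v]])
  }
  for (v in order) {
    ch <- tree$children[[v]]
    if (length(ch) == 0L) {
      if (task_of_leaf[v] == 0L) stop("leaf node without a task")
      groups[[v]] <- task_of_leaf[v]
      heights[v] <- 1L
    } else {
      groups[[v]] <- sort(unlist(groups[ch]))
      heights[v] <- 1L + max(heights[ch])
    }
  }
  if (length(groups[[tree$root]]) != length(tree$cell_ids))
    stop("root group does not cover all tasks")
  w <- as.numeric(heights)
  if (normalize) w <- w / w[tree$root]
  tree$groups <- groups
  tree$heights <- heights
  tree$weights <- w
  tree$prox_order <- order(heights)  # leaves first, root last
  tree
}

.hclust_to_tasktree <- function(hc, cell_ids) {
  k <- length(cell_ids)
  n <- 2L * k - 1L
  parent <- rep(NA_integer_, n)
  for (i in seq_len(k - 1L)) {
    for (child in hc$merge[i, ]) {
      id <- if (child < 0) -child else k + child
      parent[id] <- k + i
    }
  }
  # leaves appear in hc$labels order == cell_ids order
  new_task_tree(parent, cell_ids, seq_len(k))
}

#' Hierarchical-clustering task tree from expression
#'
#' Agglomerative clustering of cells with complete linkage on the
#' dissimilarity `1 - Pearson(cell_i, cell_j)` computed across genes; the
#' dendrogram (all binary merge nodes retained) becomes the task tree.
#'
#' @param expr An `ExpressionMatrix` (genes x cells).
#' @param normalize Passed to [compute_groups_and_weights()].
#' @return A `TaskTree` with groups and weights filled.
#' @export
build_hc_tree <- function(expr, normalize = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  if (ncol(v) < 2L) stop("need at least 2 cells")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant expression in cell(s) ",
         paste(colnames(v)[sds == 0], collapse = ", "),
         "; correlation dissimilarity undefined")
  d <- stats::as.dist(1 - stats::cor(v))
  hc <- stats::hclust(d, method = "complete")
  compute_groups_and_weights(.hclust_to_tasktree(hc, colnames(v)),
                             normalize = normalize)
}

#' Task tree from a 2-D cell embedding
#'
#' Applies the same complete-linkage agglomeration as [build_hc_tree()] to
#' externally produced 2-D cell coordinates (e.g. a pseudotime embedding),
#' using Euclidean distance: with only two dimensions a correlation
#' dissimilarity is degenerate, while a metric one separates distant point
#' clouds first.
#'
#' @param coords Numeric k x 2 matrix/data frame with cell ids as
#'   rownames (or a `cell_id` first column).
#' @param normalize Passed to [compute_groups_and_weights()].
#' @return A `TaskTree`.
#' @export
build_embedding_tree <- function(coords, normalize = FALSE) {
  if (is.data.frame(coords) && is.character(coords[[1L]])) {
    rn <- coords[[1L]]
    coords <- as.matrix(coords[, -1L, drop = FALSE])
    rownames(coords) <- rn
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have exactly 2 dimensions")
  if (is.null(rownames(coords))) stop("coords need cell ids as rownames")
  if (anyDuplicated(rownames(coords))) stop("duplicated cell ids in coords")
  if (nrow(coords) < 2L) stop("need at least 2 cells")
  hc <- stats::hclust(stats::dist(coords), method = "complete")
  compute_groups_and_weights(.hclust_to_tasktree(hc, rownames(coords)),
                             normalize = normalize)
}

#' Star task tree
#'
#' Root plus one leaf per cell (`k + 1` nodes); the baseline structure that
#' imposes no grouping beyond "all cells".
#'
#' @param cell_ids Character vector of cell ids.
#' @param normalize Passed to [compute_groups_and_weights()].
#' @return A `TaskTree`.
#' @export
build_star_tree <- function(cell_ids, normalize = FALSE) {
  k <- length(cell_ids)
  if (k < 1L) stop("empty cell list")
  parent <- c(NA_integer_, rep(1L, k))
  compute_groups_and_weights(
    new_task_tree(parent, cell_ids, 1L + seq_len(k)), normalize = normalize)
}

#' Shuffle expression within each cell
#'
#' Independently permutes each cell's column across genes (value multisets
#' per cell are preserved exactly). Building a task tree from the shuffled
#' matrix and refitting on it yields the randomised null model.
#'
#' @param expr An `ExpressionMatrix`.
#' @param seed Integer seed.
#' @return A new `ExpressionMatrix` with shuffled columns.
#' @export
shuffle_expression <- function(expr, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  out <- expr
  out$values <- withr::with_seed(seed,
    apply(expr$values, 2L, sample))
  dimnames(out$values) <- dimnames(expr$values)
  out
}

.newick_string <- function(tree) {
  build <- function(v) {
    ch <- tree$children[[v]]
    if (length(ch) == 0L) {
      i <- match(v, tree$leaf_nodes)
      return(tree$cell_ids[i])
    }
    paste0("(", paste(vapply(ch, build, ""), collapse = ","),
           ")n", v)
  }
  paste0(build(tree$root), ";")
}

#' Serialise a task tree as Newick plus a weight sidecar
#'
#' Writes `<path>` (Newick; internal nodes labelled `n<id>`) and
#' `<path>.weights.tsv` (`node_id`, `weight`, comma-joined `leaf_ids`).
#'
#' @param tree A `TaskTree` with groups/weights filled.
#' @param path Output Newick path.
#' @return `path`, invisibly.
#' @export
write_task_tree <- function(tree, path) {
  stopifnot(inherits(tree, "TaskTree"), !is.null(tree$weights))
  writeLines(.newick_string(tree), path)
  leaf_lab <- function(v)
    paste(tree$cell_ids[tree$groups[[v]]], collapse = ",")
  lab <- ifelse(seq_len(tree$n_nodes) %in% tree$leaf_nodes,
                tree$cell_ids[match(seq_len(tree$n_nodes), tree$leaf_nodes)],
                paste0("n", seq_len(tree$n_nodes)))
  data.table::fwrite(
    data.table::data.table(node_id = lab, weight = tree$weights,
                           leaf_ids = vapply(seq_len(tree$n_nodes),
                                             leaf_lab, "")),
    paste0(path, ".weights.tsv"), sep = "\t")
  invisible(path)
}

#' Read a task tree written by [write_task_tree()]
#'
#' Topology is parsed with \pkg{ape}; weights are restored from the
#' sidecar when present, otherwise recomputed from subtree heights.
#'
#' @param path Newick path.
#' @return A `TaskTree`.
#' @export
read_task_tree <- function(path) {
  ph <- ape::read.tree(path)
  if (is.null(ph)) stop("could not parse Newick file ", path)
  k <- length(ph$tip.label)
  n <- k + ph$Nnode
  parent <- rep(NA_integer_, n)
  parent[ph$edge[, 2L]] <- ph$edge[, 1L]
  tree <- new_task_tree(parent, ph$tip.label, seq_len(k))
  tree <- compute_groups_and_weights(tree)
  sidecar <- paste0(path, ".weights.tsv")
  if (file.exists(sidecar)) {
    w <- data.table::fread(sidecar)
    # match by leaf-set signature, robust to node renumbering
    sig <- vapply(tree$groups, function(g)
      paste(sort(tree$cell_ids[g]), collapse = ","), "")
    wsig <- vapply(strsplit(w$leaf_ids, ","), function(x)
      paste(sort(x), collapse = ","), "")
    idx <- match(sig, wsig)
    if (!anyNA(idx)) tree$weights <- w$weight[idx]
  }
  tree
}
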