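#' Synthetic multi-task regression fixture with planted structure
#'
#' Generates the data model the multi-task framework assumes: a
#' nonnegative, affinity-like feature matrix `X` (folded-normal draws,
#' right-skewed like biophysical binding scores), a block-structured
#' coefficient matrix `B` in which each cell cluster has its own small set
#' of active TFs, and responses `Y = X B + N(0, noise_sd^2)`. A matched TF
#' expression matrix is produced in which each planted TF is expressed
#' more highly in the cells of its own cluster, so the downstream
#' sign-consistency analysis has a defined ground truth.
#'
#' @param n Number of genes; default 500.
#' @param p Number of TFs/features; default 50.
#' @param k Number of cells (tasks), divisible by `n_clusters`; default 40.
#' @param n_clusters Number of cell clusters; default 2.
#' @param tfs_per_cluster Active TFs planted per cluster; default 5.
#' @param effect_size Coefficient value of the planted entries; default 1.
#' @param noise_sd Gaussian noise standard deviation; default 0.1.
#' @param seed Integer seed; the fixture is a pure function of its
#'   arguments and the seed.
#' @return List with `X` (`FeatureMatrix`), `Y` (`ExpressionMatrix`,
#'   log2-scale responses with the cluster as `cell_labels`),
#'   `tf_expression` (p x k log2-scale matrix), `truth` (planted `B`,
#'   cluster map, per-cluster active TF sets, noise and seed) and `tree`
#'   (the reference `TaskTree`: clusters under a root).
#' @export
generate_regression_fixture <- function(n = 500L, p = 50L, k = 40L,
                                        n_clusters = 2L,
                                        tfs_per_cluster = 5L,
                                        effect_size = 1, noise_sd = 0.1,
                                        seed = 1L) {
  if (k %% n_clusters != 0L) stop("k must be divisible by n_clusters")
  if (n_clusters * tfs_per_cluster > p)
    stop("more planted TFs than features")
  if (effect_size == 0) warning("effect_size 0: nothing planted to recover")
  gene_ids <- sprintf("gene%03d", seq_len(n))
  tf_ids <- sprintf("TF%02d", seq_len(p))
  cell_ids <- sprintf("cell%02d", seq_len(k))
  per <- k %/% n_clusters
  cluster <- stats::setNames(rep(seq_len(n_clusters), each = per), cell_ids)
  B_true <- matrix(0, p, k, dimnames = list(tf_ids, cell_ids))
  active <- vector("list", n_clusters)
  for (c in seq_len(n_clusters)) {
    rows <- ((c - 1L) * tfs_per_cluster + 1L):(c * tfs_per_cluster)
    B_true[rows, cluster == c] <- effect_size
    active[[c]] <- tf_ids[rows]
  }
  out <- withr::with_seed(seed, {
    X <- matrix(abs(stats::rnorm(n * p)), n, p,
                dimnames = list(gene_ids, tf_ids))
    Y <- X %*% B_true + matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
    # TF expression: baseline folded-normal, planted TFs elevated in their
    # own cluster in proportion to effect_size.
    E <- matrix(abs(stats::rnorm(p * k, sd = 0.5)), p, k,
                dimnames = list(tf_ids, cell_ids))
    for (c in seq_len(n_clusters))
      E[active[[c]], cluster == c] <-
        E[active[[c]], cluster == c] + 2 * abs(effect_size)
    list(X = X, Y = Y, E = E)
  })
  colnames(out$Y) <- cell_ids
  # reference tree: root (1) -> cluster nodes -> leaves
  parent <- c(NA_integer_, rep(1L, n_clusters),
              1L + unname(cluster))
  tree <- compute_groups_and_weights(
    new_task_tree(parent, cell_ids, 1L + n_clusters + seq_len(k)))
  list(X = new_feature_matrix(out$X, "static"),
       Y = new_expression_matrix(out$Y, scale_flag = "log2",
                                 cell_labels = stats::setNames(
                                   as.character(cluster), names(cluster))),
       tf_expression = out$E,
       truth = list(true_B = B_true, cell_clusters = cluster,
                    active_tfs = active, effect_size = effect_size,
                    noise_sd = noise_sd, seed = seed),
       tree = tree)
}

#' Synthetic TPM matrix with dropout and planted filter failures
#'
#' Log-normal TPM values masked to zero by independent Bernoulli dropout,
#' plus a known subset of genes constructed to fail the detected-gene rule
#' (expressed at or above `detected_floor` in fewer than 10 cells).
#'
#' @param n Number of genes; default 500.
#' @param k Number of cells; default 60.
#' @param dropout_rate Probability that an entry is zeroed; default 0.3.
#' @param detected_floor Detection threshold the planted-fail genes are
#'   built against; default 0.1 TPM.
#' @param n_fail Number of planted-fail genes; default `round(0.05 * n)`.
#' @param seed Integer seed.
#' @return List with `expr` (an `ExpressionMatrix`, TPM scale) and
#'   `planted_fail` (ids of the genes built to fail the filter).
#' @export
generate_tpm_fixture <- function(n = 500L, k = 60L, dropout_rate = 0.3,
                                 detected_floor = 0.1,
                                 n_fail = max(1L, round(0.05 * n)),
                                 seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  gene_ids <- sprintf("gene%04d", seq_len(n))
  cell_ids <- sprintf("cell%03d", seq_len(k))
  vals <- withr::with_seed(seed, {
    v <- matrix(stats::rlnorm(n * k, meanlog = 1, sdlog = 1), n, k)
    v[matrix(stats::runif(n * k) < dropout_rate, n, k)] <- 0
    fail_rows <- sample.int(n, n_fail)
    detectable <- min(9L, k)
    for (r in fail_rows) {
      v[r, ] <- 0
      on_cells <- sample.int(k, detectable)
      v[r, on_cells] <- detected_floor * 10
    }
    attr(v, "fail_rows") <- fail_rows
    v
  })
  fail_rows <- attr(vals, "fail_rows")
  attr(vals, "fail_rows") <- NULL
  dimnames(vals) <- list(gene_ids, cell_ids)
  list(expr = new_expression_matrix(vals, "tpm"),
       planted_fail = gene_ids[sort(fail_rows)])
}

.random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.sharp_pwm <- function(name, length_motif = 10L, dominance = 0.85) {
  cons <- sample.int(4L, length_motif, replace = TRUE)
  m <- matrix((1 - dominance) / 3, 4L, length_motif)
  m[cbind(cons, seq_len(length_motif))] <- dominance
  new_pwm(name, m * 100)
}

#' Synthetic genomic fixture for the feature builders
#'
#' A random single-chromosome genome with evenly spaced TSSs, sharp random
#' motifs, an exact consensus of the first motif planted just downstream
#' of the TSS of the first half of the genes, open-chromatin peaks at
#' known offsets around each TSS (so decay-weighted sums have closed-form
#' oracle values), and per-TF count-carrying peaks for the ChIP flavour.
#'
#' @param n_genes Number of genes; default 12.
#' @param n_tfs Number of motifs; default 4.
#' @param n_peaks Number of open-chromatin peaks; default 30.
#' @param chrom_length Chromosome length in bp; must fit all windows.
#' @param seed Integer seed.
#' @return List with `genome` (`DNAStringSet`), `genes` (annotation data
#'   frame), `pwms`, `peaks` (data frame with `signal`), `tf_peaks`
#'   (named list with `count`) and `planted` (ids of motif-carrying
#'   genes).
#' @export
generate_genomic_fixture <- function(n_genes = 12L, n_tfs = 4L,
                                     n_peaks = 30L,
                                     chrom_length = 120000L, seed = 1L) {
  spacing <- chrom_length %/% (n_genes + 1L)
  if (spacing < 4000L) stop("chrom_length too small for the gene windows")
  withr::with_seed(seed, {
    seq <- .random_genome(chrom_length)
    pwms <- lapply(seq_len(n_tfs), function(i) .sharp_pwm(sprintf("TF%02d", i)))
    names(pwms) <- vapply(pwms, `[[`, "", "tf_name")
    tss <- spacing * seq_len(n_genes)
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                        chrom = "chrS", tss = tss, strand = "+",
                        stringsAsFactors = FALSE)
    planted <- genes$gene_id[seq_len(n_genes %/% 2L)]
    cons <- consensus(pwms[[1L]])
    planted_at <- integer(0)
    for (i in seq_len(n_genes %/% 2L)) {
      at <- tss[i] + 10L  # 0-based offset inside every window flavour
      substr(seq, at + 1L, at + nchar(cons)) <- cons
      planted_at <- c(planted_at, at + 1L)
    }
    # scrub chance occurrences of the planted motif (either strand) so the
    # planted/background contrast holds by construction
    shift_base <- c(A = "C", C = "G", G = "T", T = "A")
    for (pat in unique(c(cons, .revcomp(cons)))) {
      for (iter in 1:10) {
        hits <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
        hits <- setdiff(hits[hits > 0], if (pat == cons) planted_at)
        if (!length(hits)) break
        for (h in hits) {
          mid <- h + nchar(pat) %/% 2L
          substr(seq, mid, mid) <- shift_base[[substr(seq, mid, mid)]]
        }
      }
    }
    offs <- sample(seq(-20000L, 20000L, by = 500L), n_peaks, replace = TRUE)
    anchor <- sample(tss, n_peaks, replace = TRUE)
    ps <- pmax(0L, anchor + offs - 150L)
    peaks <- data.frame(chrom = "chrS", start = ps, end = ps + 300L,
                        signal = round(stats::runif(n_peaks, 1, 50), 2),
                        stringsAsFactors = FALSE)
    tf_peaks <- lapply(seq_len(n_tfs), function(t) {
      m <- 2L * n_genes
      a <- sample(tss, m, replace = TRUE) +
        sample(seq(-2000L, 2000L, by = 100L), m, replace = TRUE)
      a <- pmax(0L, a)
      data.frame(chrom = "chrS", start = a, end = a + 200L,
                 count = stats::rpois(m, 20), stringsAsFactors = FALSE)
    })
    names(tf_peaks) <- names(pwms)
    genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chrS"))
    list(genome = genome, genes = genes, pwms = pwms, peaks = peaks,
         tf_peaks = tf_peaks, planted = planted)
  })
}
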