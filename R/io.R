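#' Read a gene x cell expression table
#'
#' Accepts a TSV with a header of cell ids and gene ids in the first
#' column, or a matrix-market triplet file accompanied by one-id-per-line
#' row (gene) and column (cell) files.
#'
#' @param path TSV or `.mtx` path.
#' @param scale_flag `"tpm"` (default) or `"log2"`.
#' @param row_ids,col_ids Id files, required for matrix-market input.
#' @param labels Optional TSV (`cell_id`, `label`) of cell types.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, scale_flag = "tpm", row_ids = NULL,
                            col_ids = NULL, labels = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(row_ids) || is.null(col_ids))
      stop("matrix-market input needs row_ids and col_ids files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_ids)
    colnames(m) <- readLines(col_ids)
  } else {
    m <- .read_matrix_tsv(path)
  }
  lab <- NULL
  if (!is.null(labels)) {
    lt <- data.table::fread(labels, header = TRUE)
    lab <- stats::setNames(as.character(lt[[2L]]), lt[[1L]])
  }
  new_expression_matrix(m, scale_flag = scale_flag, cell_labels = lab)
}

.read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- ids
  m
}

.write_matrix_tsv <- function(m, path, id_col = "id") {
  dt <- data.table::data.table(rownames(m))
  data.table::setnames(dt, id_col)
  data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path,
                     sep = "\t")
  invisible(path)
}

#' Write an expression matrix as TSV
#' @param expr An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  .write_matrix_tsv(expr$values, path, "gene_id")
}

#' Read a feature matrix TSV (gene ids in the first column)
#' @param path Input TSV.
#' @param flavour Feature flavour; inferred as `"dynamic"` when the
#'   `Peak_*` columns are present, else `"static"` unless given.
#' @return A `FeatureMatrix`.
#' @export
read_feature_matrix <- function(path, flavour = NULL) {
  m <- .read_matrix_tsv(path)
  if (is.null(flavour))
    flavour <- if (all(c("Peak_Counts", "Peak_Length", "Peak_Signal") %in%
                         colnames(m))) "dynamic" else "static"
  new_feature_matrix(m, flavour)
}

#' Write a feature matrix as TSV
#' @param fm A `FeatureMatrix`.
#' @param path Output path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  .write_matrix_tsv(fm$values, path, "gene_id")
}

#' Read gene annotation from BED6
#'
#' Columns: chrom, start, end, name (gene id), score, strand; 0-based
#' half-open. The TSS is the interval start for `+` genes and `end - 1`
#' for `-` genes.
#'
#' @param path BED6 path.
#' @return Data frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_annotation <- function(path) {
  bed <- data.table::fread(path, header = FALSE)
  if (ncol(bed) < 6L) stop("annotation must be BED6 (6+ columns)")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(bed$end <= bed$start)) {
    bad <- which(bed$end <= bed$start)[1L]
    stop("end <= start at line ", bad, " of ", path)
  }
  if (!all(bed$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  if (anyDuplicated(bed$name)) stop("duplicate gene ids in ", path)
  data.frame(gene_id = as.character(bed$name), chrom = as.character(bed$chrom),
             tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             strand = as.character(bed$strand), stringsAsFactors = FALSE)
}

#' Read peaks from BED or narrowPeak
#'
#' 0-based half-open intervals. For 10-column narrowPeak input the
#' `signalValue` (column 7) becomes `signal`; for plain BED a `signal`
#' column may be named via `signal_col`, and a count column (ChIP flavour)
#' via `count_col`.
#'
#' @param path BED/narrowPeak path.
#' @param signal_col,count_col Optional 1-based column indices.
#' @return Data frame with `chrom`, `start`, `end` and any of `signal`,
#'   `count`.
#' @export
read_peaks <- function(path, signal_col = NULL, count_col = NULL) {
  bed <- data.table::fread(path, header = FALSE)
  if (ncol(bed) < 3L) stop("peak file needs at least 3 columns")
  out <- data.frame(chrom = as.character(bed[[1L]]), start = bed[[2L]],
                    end = bed[[3L]], stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1L]
    stop("end <= start at line ", bad, " of ", path)
  }
  if (ncol(bed) == 10L && is.null(signal_col)) signal_col <- 7L
  if (!is.null(signal_col)) out$signal <- as.numeric(bed[[signal_col]])
  if (!is.null(count_col)) out$count <- as.numeric(bed[[count_col]])
  out
}

#' Read a 2-D cell embedding (TSV: cell_id, dim1, dim2)
#' @param path Input TSV.
#' @return k x 2 numeric matrix with cell ids as rownames.
#' @export
read_coords <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 3L) stop("coords need cell_id, dim1, dim2")
  if (anyDuplicated(dt[[1L]])) stop("duplicated cell ids in ", path)
  m <- as.matrix(dt[, 2:3])
  rownames(m) <- as.character(dt[[1L]])
  m
}

#' Read and validate a pipeline configuration (JSON)
#'
#' @param path JSON file of [run_pipeline()] settings.
#' @return Named list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
validate_config <- function(cfg) {
  defaults <- list(tree = "hc", model = "tree",
                   lambda_grid = default_lambda_grid(), folds = 5L,
                   seed = 1L, min_expr = 0.1, min_cells = 10L,
                   log2_pseudocount = 1, train_frac = 0.6,
                   subsample_cells = 1, heatmap_threshold = 0.5,
                   scaling = "maxabs", sig_level = 0.1,
                   with_null_model = FALSE, max_iter = 1000L, tol = 1e-6)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(cfg$tree %in% c("hc", "star", "rtree", "embedding"),
            cfg$model %in% c("tree", "omtl", "stl"),
            length(cfg$lambda_grid) > 0,
            cfg$subsample_cells > 0, cfg$subsample_cells <= 1)
  for (f in c("expression", "features", "coords", "labels"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured ", f, " file does not exist: ", cfg[[f]])
  if (is.null(cfg$expression) && is.null(cfg$simulate))
    stop("config needs either input paths or a 'simulate' block")
  cfg
}

.log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  message(msg)
  c(log, msg)
}

#' Run the full workflow
#'
#' Chains the stages end to end: load (or simulate) expression and
#' features, optional seeded cell subsampling, the filter cascade
#' (detected genes on raw TPM, feature-variance, zero-expression TF
#' removal, log2 transform), the 60/40 gene split, standardisation on
#' training genes, task-tree construction, model fitting (with
#' cross-validation for the tree model), test-set evaluation and the
#' activity report. All randomness derives from `config$seed`; identical
#' configurations give identical outputs.
#'
#' @param config List from [read_config()]/[validate_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing.
#' @return Invisibly, a list with the fit, evaluation, report and run
#'   log.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  log <- character(0)
  stage <- "load"
  result <- tryCatch({
    if (!is.null(cfg$simulate)) {
      sim <- do.call(generate_regression_fixture,
                     c(cfg$simulate, list(seed = cfg$seed)))
      expr <- sim$Y
      fm <- sim$X
      tf_expression <- sim$tf_expression
      log <- .log_stage(log, stage, "simulated fixture, ",
                        nrow(fm$values), " genes x ", ncol(expr$values),
                        " cells")
      already_log2 <- TRUE
    } else {
      expr <- read_expression(cfg$expression, labels = cfg$labels)
      fm <- read_feature_matrix(cfg$features)
      tf_expression <- NULL
      already_log2 <- identical(expr$scale_flag, "log2")
      log <- .log_stage(log, stage, "read ", nrow(fm$values), " genes x ",
                        ncol(expr$values), " cells")
    }
    if (cfg$subsample_cells < 1) {
      stage <- "subsample"
      k <- ncol(expr$values)
      keep <- sort(withr::with_seed(cfg$seed + 1L,
        sample.int(k, round(cfg$subsample_cells * k))))
      expr$values <- expr$values[, keep, drop = FALSE]
      if (!is.null(expr$cell_labels))
        expr$cell_labels <- expr$cell_labels[keep]
      if (!is.null(tf_expression))
        tf_expression <- tf_expression[, keep, drop = FALSE]
      log <- .log_stage(log, stage, length(keep), " cells retained")
    }
    stage <- "filter"
    if (!already_log2) {
      det <- detect_gene_filter(expr, cfg$min_expr, cfg$min_cells)
      expr$values <- expr$values[det$kept_genes, , drop = FALSE]
      log <- .log_stage(log, stage, "detected-gene filter kept ",
                        length(det$kept_genes), " genes")
    } else det <- NULL
    common <- intersect(rownames(fm$values), rownames(expr$values))
    fm$values <- fm$values[common, , drop = FALSE]
    expr$values <- expr$values[common, , drop = FALSE]
    vf <- variance_filter(fm)
    fm$values <- fm$values[vf$kept_genes, , drop = FALSE]
    expr$values <- expr$values[vf$kept_genes, , drop = FALSE]
    if (is.null(cfg$simulate)) {
      # simulated fixtures carry TF expression separately; the TF-dropout
      # rule only applies when feature ids map to measured genes
      tg_map <- if (!is.null(cfg$tf_gene_map)) {
        mp <- data.table::fread(cfg$tf_gene_map, header = TRUE)
        stats::setNames(as.character(mp[[2L]]), mp[[1L]])
      } else NULL
      fm <- drop_zero_expression_tfs(fm, expr, tg_map)
    }
    log <- .log_stage(log, stage, "variance filter kept ",
                      length(vf$kept_genes), " genes, ",
                      ncol(fm$values), " features retained")
    if (!already_log2) {
      fm <- log2_transform(fm, cfg$log2_pseudocount)
      expr <- log2_transform(expr, cfg$log2_pseudocount)
    }
    stage <- "split"
    split <- split_train_test(nrow(fm$values), frac = cfg$train_frac,
                              seed = cfg$seed + 2L)
    st <- standardize(fm$values, expr$values, split$train)
    log <- .log_stage(log, stage, length(split$train), " train / ",
                      length(split$test), " test genes")
    stage <- "tree"
    train_expr <- expr
    if (cfg$tree == "rtree") {
      train_expr <- shuffle_expression(expr, seed = cfg$seed + 3L)
      st <- standardize(fm$values, train_expr$values, split$train)
    }
    tree <- switch(cfg$tree,
      hc = , rtree = build_hc_tree(train_expr),
      star = build_star_tree(colnames(train_expr$values)),
      embedding = build_embedding_tree(read_coords(cfg$coords)))
    log <- .log_stage(log, stage, cfg$tree, " tree with ", tree$n_nodes,
                      " nodes")
    stage <- "train"
    Xtr <- st$X[match(split$train, seq_len(nrow(fm$values))), , drop = FALSE]
    Ytr <- st$Y[match(split$train, seq_len(nrow(fm$values))), , drop = FALSE]
    Xte <- st$X[match(split$test, seq_len(nrow(fm$values))), , drop = FALSE]
    Yte_raw <- train_expr$values[split$test, colnames(st$Y), drop = FALSE]
    cv <- NULL
    if (cfg$model == "tree") {
      cv <- cross_validate_tree(Xtr, Ytr, tree, cfg$lambda_grid,
                                folds = cfg$folds, seed = cfg$seed + 4L,
                                max_iter = cfg$max_iter, tol = cfg$tol)
      fit <- fit_tree_guided(Xtr, Ytr, tree, cv$selected,
                             max_iter = cfg$max_iter, tol = cfg$tol)
      log <- .log_stage(log, stage, "selected lambda ", cv$selected)
    } else if (cfg$model == "omtl") {
      cv <- cross_validate_omtl(Xtr, Ytr, seq(0, 1, by = 0.05),
                                folds = cfg$folds, seed = cfg$seed + 4L,
                                max_iter = cfg$max_iter, tol = cfg$tol)
      fit <- fit_omtl(Xtr, Ytr, cv$selected, max_iter = cfg$max_iter,
                      tol = cfg$tol)
      log <- .log_stage(log, stage, "selected alpha ", cv$selected)
    } else {
      Bs <- vapply(seq_len(ncol(Ytr)), function(j)
        fit_stl(Xtr, Ytr[, j], folds = cfg$folds,
                seed = cfg$seed + 4L)$B[, 1L], numeric(ncol(Xtr)))
      dimnames(Bs) <- list(colnames(Xtr), colnames(Ytr))
      fit <- .new_fit(Bs, "stl", NA_real_, NA_real_, NULL, NA_real_,
                      TRUE, 0L)
      log <- .log_stage(log, stage, "fitted ", ncol(Ytr), " STL models")
    }
    fit$standardization <- st
    fit$split <- split
    fit$cv <- cv
    stage <- "evaluate"
    Yhat_std <- Xte %*% fit$B
    Yhat <- destandardize_response(st, Yhat_std)
    r <- evaluate_per_cell(Yhat, Yte_raw)
    log <- .log_stage(log, stage, "median per-cell r = ",
                      signif(stats::median(r, na.rm = TRUE), 4))
    stage <- "interpret"
    report <- activity_report(fit, cell_labels = expr$cell_labels,
                              tf_expression = tf_expression,
                              heatmap_threshold = cfg$heatmap_threshold,
                              scaling = cfg$scaling,
                              sig_level = cfg$sig_level)
    list(fit = fit, tree = tree, evaluation = r, report = report,
         filter = list(detect = det, variance = vf), log = log)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_matrix_tsv(result$fit$B, file.path(out_dir, "coefficients.tsv"),
                      "feature_id")
    data.table::fwrite(data.table::data.table(
      cell_id = names(result$evaluation),
      pearson_r = as.numeric(result$evaluation)),
      file.path(out_dir, "evaluation.tsv"), sep = "\t")
    data.table::fwrite(result$report, file.path(out_dir, "activity_report.tsv"),
                       sep = "\t")
    write_task_tree(result$tree, file.path(out_dir, "tree.nwk"))
    split_dt <- data.table::data.table(
      gene_index = c(result$fit$split$train, result$fit$split$test),
      partition = rep(c("train", "test"),
                      c(length(result$fit$split$train),
                        length(result$fit$split$test))))
    data.table::fwrite(split_dt, file.path(out_dir, "split.tsv"), sep = "\t")
    jsonlite::write_json(
      list(lambda = result$fit$lambda, model = result$fit$model_kind,
           seed = config$seed),
      file.path(out_dir, "fit_params.json"), auto_unbox = TRUE)
    writeLines(result$log, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

#' Cross-validate the ordinary-MTL penalty
#'
#' Same gene-wise fold scheme as [cross_validate_tree()], applied to
#' [fit_omtl()] over an alpha grid (default 0 to 1 at step 0.05).
#'
#' @inheritParams cross_validate_tree
#' @param alpha_grid Candidate penalty strengths.
#' @return A `CvResult`.
#' @export
cross_validate_omtl <- function(X, Y, alpha_grid = seq(0, 1, by = 0.05),
                                folds = 5L, seed = 1L, max_iter = 1000L,
                                tol = 1e-6) {
  if (length(alpha_grid) == 0L) stop("empty alpha grid")
  alpha_grid <- sort(alpha_grid)
  foldid <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = nrow(X))))
  fold_loss <- matrix(NA_real_, folds, length(alpha_grid))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    B0 <- NULL
    for (ai in seq_along(alpha_grid)) {
      fit <- fit_omtl(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      alpha_grid[ai], max_iter = max_iter, tol = tol,
                      B_init = B0)
      B0 <- fit$B
      resid <- Y[!tr, , drop = FALSE] - X[!tr, , drop = FALSE] %*% fit$B
      fold_loss[f, ai] <- mean(resid^2)
    }
  }
  mean_loss <- colMeans(fold_loss)
  structure(list(lambda_grid = alpha_grid, mean_loss = mean_loss,
                 fold_loss = fold_loss,
                 selected = alpha_grid[which.min(mean_loss)],
                 foldid = foldid, seed = seed),
            class = "CvResult")
}
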