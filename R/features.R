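#' Gene x TF feature matrix
#'
#' Container for the three feature flavours: `static` (promoter-window
#' binding affinities), `dynamic` (open-chromatin peak affinities with
#' distance decay plus the three `Peak_*` summary columns) and `chipseq`
#' (summed peak read counts near the TSS).
#'
#' @param values Numeric genes x features matrix with unique dimnames.
#' @param flavour One of `"static"`, `"dynamic"`, `"chipseq"`.
#' @return A `FeatureMatrix` object: list with `values` and `flavour`.
#' @export
new_feature_matrix <- function(values,
                               flavour = c("static", "dynamic", "chipseq")) {
  flavour <- match.arg(flavour)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("FeatureMatrix needs gene and feature ids as dimnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate gene or feature ids")
  if (anyNA(values)) stop("FeatureMatrix must not contain missing values")
  if (flavour == "dynamic" &&
      !all(c("Peak_Counts", "Peak_Length", "Peak_Signal") %in%
             colnames(values)))
    stop("dynamic FeatureMatrix requires Peak_Counts/Peak_Length/Peak_Signal")
  structure(list(values = values, flavour = flavour),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix> %d genes x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$flavour))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

.check_genes <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "tss") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (any(genes$tss < 0)) stop("negative TSS coordinate")
  genes
}

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

# 0-based half-open [start, end) on `chrom`, clipped to the chromosome.
.fetch_window <- function(genome, chrom, start, end) {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  s <- max(0L, start)
  e <- min(len, end)
  if (e <= s) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start = s + 1L, end = e))
}

#' Promoter-window ("static") TF affinity features
#'
#' For every gene, binding affinities of each PWM are computed over the
#' window `[tss - half_window, tss + half_window)` centred at the TSS
#' (0-based half-open coordinates). Genes on chromosomes absent from the
#' genome are dropped with a warning; windows overhanging a chromosome end
#' are truncated.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `tss` (0-based)
#'   and optionally `strand`.
#' @param genome `DNAStringSet` or path to a FASTA file.
#' @param pwms List of `Pwm` objects.
#' @param half_window Half-width in bp; default 1000 (a 2 kb window).
#' @param lambda_trap,ln_r0 Passed to [trap_affinity()].
#' @return A `FeatureMatrix` with flavour `"static"`.
#' @export
build_static_features <- function(genes, genome, pwms, half_window = 1000L,
                                  lambda_trap = 0.7, ln_r0 = NULL) {
  genes <- .check_genes(genes)
  genome <- .as_genome(genome)
  if (length(pwms) == 0L) stop("at least one PWM is required")
  stopifnot(all(vapply(pwms, inherits, TRUE, "Pwm")))
  missing <- !(genes$chrom %in% names(genome))
  if (any(missing)) {
    warning("dropping ", sum(missing), " gene(s) on missing chromosome(s): ",
            paste(utils::head(genes$gene_id[missing], 5L), collapse = ", "))
    genes <- genes[!missing, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("no genes left after chromosome check")
  tf_names <- vapply(pwms, `[[`, "", "tf_name")
  vals <- matrix(0, nrow(genes), length(pwms),
                 dimnames = list(genes$gene_id, tf_names))
  for (g in seq_len(nrow(genes))) {
    win <- .fetch_window(genome, genes$chrom[g],
                         genes$tss[g] - half_window,
                         genes$tss[g] + half_window)
    for (t in seq_along(pwms))
      vals[g, t] <- trap_affinity(win, pwms[[t]],
                                  lambda_trap = lambda_trap, ln_r0 = ln_r0)
  }
  new_feature_matrix(vals, "static")
}

#' Exponential distance-decay weight
#'
#' Weight `exp(-distance / d0)` applied to a peak's affinity contribution,
#' with `distance` the bp separation between the TSS and the peak centre.
#'
#' @param distance Nonnegative distance in bp.
#' @param d0 Decay constant in bp (> 0); default 5000.
#' @return Value in (0, 1].
#' @examples
#' decay_weight(0, 5000)      # 1
#' decay_weight(5000, 5000)   # exp(-1)
#' @export
decay_weight <- function(distance, d0 = 5000) {
  if (any(distance < 0)) stop("distance must be nonnegative")
  if (d0 <= 0) stop("d0 must be positive")
  exp(-distance / d0)
}

.check_peaks <- function(peaks, need_signal = FALSE) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$end <= peaks$start)) stop("peak with end <= start")
  if (need_signal && is.null(peaks$signal))
    stop("peaks lack a 'signal' column required for Peak_Signal")
  peaks
}

# Half-open interval overlap via IRanges after shifting to 1-based closed.
.overlap_hits <- function(win_chrom, win_start, win_end, pk) {
  wgr <- GenomicRanges::GRanges(win_chrom,
                                IRanges::IRanges(win_start + 1L, win_end))
  pgr <- GenomicRanges::GRanges(pk$chrom,
                                IRanges::IRanges(pk$start + 1L, pk$end))
  GenomicRanges::findOverlaps(wgr, pgr)
}

#' Open-chromatin ("dynamic") TF affinity features
#'
#' For every gene, each TF's entry is the sum over open-chromatin peaks
#' overlapping the `2 * half_window` window around the TSS of the peak's
#' full-sequence affinity multiplied by [decay_weight()] of the TSS-to-peak
#' centre distance. Three extra columns summarise chromatin openness:
#' `Peak_Counts` (number of overlapping peaks), `Peak_Length` (summed
#' overlap length in bp, window-clipped) and `Peak_Signal` (summed peak
#' signal). Affinities are computed on the whole peak even when it only
#' partly overlaps the window; motif context should not be truncated.
#'
#' @inheritParams build_static_features
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `signal`.
#' @param half_window Half-width in bp; default 25000 (a 50 kb window).
#' @param d0 Decay constant; default 5000 bp.
#' @return A `FeatureMatrix` with flavour `"dynamic"`.
#' @export
build_dynamic_features <- function(genes, genome, pwms, peaks,
                                   half_window = 25000L, d0 = 5000,
                                   lambda_trap = 0.7, ln_r0 = NULL) {
  genes <- .check_genes(genes)
  genome <- .as_genome(genome)
  peaks <- .check_peaks(peaks, need_signal = TRUE)
  if (length(pwms) == 0L) stop("at least one PWM is required")
  missing <- !(genes$chrom %in% names(genome))
  if (any(missing)) {
    warning("dropping ", sum(missing), " gene(s) on missing chromosome(s)")
    genes <- genes[!missing, , drop = FALSE]
  }
  tf_names <- vapply(pwms, `[[`, "", "tf_name")
  if (nrow(peaks) == 0L)
    warning("no peaks supplied; all TF columns will be zero")
  # Affinity of every peak for every TF, computed once.
  pk_aff <- matrix(0, nrow(peaks), length(pwms))
  pk_seq <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks)))
    pk_seq[i] <- .fetch_window(genome, peaks$chrom[i], peaks$start[i],
                               peaks$end[i])
  for (t in seq_along(pwms))
    pk_aff[, t] <- vapply(pk_seq, function(s)
      if (nchar(s) == 0L) 0 else trap_affinity(s, pwms[[t]],
        lambda_trap = lambda_trap, ln_r0 = ln_r0), 0, USE.NAMES = FALSE)
  centres <- floor((peaks$start + peaks$end) / 2)
  ws <- pmax(0L, genes$tss - half_window)
  we <- genes$tss + half_window
  vals <- matrix(0, nrow(genes), length(pwms) + 3L,
                 dimnames = list(genes$gene_id,
                                 c(tf_names, "Peak_Counts", "Peak_Length",
                                   "Peak_Signal")))
  if (nrow(peaks) > 0L) {
    hits <- .overlap_hits(genes$chrom, ws, we, peaks)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (g in unique(qh)) {
      pk <- sh[qh == g]
      w <- decay_weight(abs(genes$tss[g] - centres[pk]), d0 = d0)
      vals[g, seq_along(pwms)] <- colSums(pk_aff[pk, , drop = FALSE] * w)
      vals[g, "Peak_Counts"] <- length(pk)
      vals[g, "Peak_Length"] <- sum(pmin(we[g], peaks$end[pk]) -
                                      pmax(ws[g], peaks$start[pk]))
      vals[g, "Peak_Signal"] <- sum(peaks$signal[pk])
    }
  }
  new_feature_matrix(vals, "dynamic")
}

#' ChIP-seq count features
#'
#' For every gene and TF, sums the read counts of that TF's ChIP-seq peaks
#' overlapping the `2 * half_window` window around the TSS (0-based
#' half-open overlap; a peak ending exactly at the window start does not
#' overlap).
#'
#' @inheritParams build_static_features
#' @param tf_peaks Named list (one element per TF) of data frames with
#'   `chrom`, `start`, `end`, `count`.
#' @param half_window Half-width in bp; default 1500 (a 3 kb window).
#' @return A `FeatureMatrix` with flavour `"chipseq"`.
#' @export
build_chipseq_features <- function(genes, tf_peaks, half_window = 1500L) {
  genes <- .check_genes(genes)
  if (length(tf_peaks) == 0L || is.null(names(tf_peaks)))
    stop("tf_peaks must be a non-empty named list")
  ws <- pmax(0L, genes$tss - half_window)
  we <- genes$tss + half_window
  vals <- matrix(0, nrow(genes), length(tf_peaks),
                 dimnames = list(genes$gene_id, names(tf_peaks)))
  for (t in seq_along(tf_peaks)) {
    pk <- tf_peaks[[t]]
    if (is.null(pk) || nrow(pk) == 0L) {
      warning("TF '", names(tf_peaks)[t], "' has no peaks; zero column")
      next
    }
    pk <- .check_peaks(pk)
    if (is.null(pk$count) || any(pk$count < 0))
      stop("TF '", names(tf_peaks)[t], "': nonnegative 'count' column required")
    hits <- .overlap_hits(genes$chrom, ws, we, pk)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh))
      vals[, t] <- as.numeric(tapply(pk$count[sh], factor(qh,
                     levels = seq_len(nrow(genes))), sum, default = 0))
  }
  new_feature_matrix(vals, "chipseq")
}
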