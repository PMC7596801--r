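#' Position weight matrix (PWM) for a transcription factor
#'
#' Wraps a 4 x L nonnegative count/weight matrix (rows A, C, G, T) together
#' with the pseudocount used to turn it into a column-stochastic probability
#' matrix. All affinity scoring in the package goes through objects of this
#' class.
#'
#' @param tf_name Name of the transcription factor (used as feature id).
#' @param counts 4 x L numeric matrix of nonnegative weights; rows must be
#'   A, C, G, T (rownames optional but, if present, must be in that order).
#' @param pseudocount Positive value added to every cell before column
#'   normalisation. Default 0.01.
#' @return An object of class `Pwm` with elements `tf_name`, `counts`,
#'   `prob` (column-normalised probabilities), `pseudocount`, `length`.
#' @examples
#' m <- matrix(c(10, 0, 0, 0,  0, 10, 0, 0), nrow = 4)
#' p <- new_pwm("TF1", m)
#' consensus(p)
#' @export
new_pwm <- function(tf_name, counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop("PWM must be a 4 x L matrix with L >= 1")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("PWM weights must be finite and nonnegative")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), c("A", "C", "G", "T")))
    stop("PWM rows must be ordered A, C, G, T")
  rownames(counts) <- c("A", "C", "G", "T")
  shifted <- counts + pseudocount
  prob <- sweep(shifted, 2L, colSums(shifted), "/")
  stopifnot(all(abs(colSums(prob) - 1) < 1e-9))
  structure(
    list(tf_name = tf_name, counts = counts, prob = prob,
         pseudocount = pseudocount, length = ncol(counts)),
    class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("<Pwm> %s (length %d, pseudocount %g)\n",
              x$tf_name, x$length, x$pseudocount))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A [new_pwm()] object.
#' @return Character string of the per-column most probable base.
#' @export
consensus <- function(pwm) {
  stopifnot(inherits(pwm, "Pwm"))
  paste(rownames(pwm$prob)[apply(pwm$prob, 2L, which.max)], collapse = "")
}

#' Read transcription factor motifs from JASPAR-style PFM text
#'
#' Accepts both the bracketed dialect (`>MA0001.1 NAME` followed by
#' `A [ 1 2 3 ]` ...) and the bare dialect (header line followed by four
#' unlabelled numeric rows).
#'
#' @param path Path to a PFM text file possibly holding several motifs.
#' @param pseudocount Passed to [new_pwm()].
#' @return A named list of `Pwm` objects.
#' @export
read_pfm <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' motif headers found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  pwms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop("motif '", name, "': expected 4 matrix rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("[][ACGTacgt]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif '", name, "': ragged matrix rows")
    pwms[[i]] <- new_pwm(name, do.call(rbind, rows), pseudocount = pseudocount)
  }
  names(pwms) <- vapply(pwms, `[[`, "", "tf_name")
  if (anyDuplicated(names(pwms))) stop("duplicate motif names in ", path)
  pwms
}

#' Write motifs in bracketed JASPAR-style PFM text
#'
#' @param pwms List of `Pwm` objects.
#' @param path Output file.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    stopifnot(inherits(p, "Pwm"))
    writeLines(paste0(">", p$tf_name, " ", p$tf_name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

.BASES <- c("A", "C", "G", "T")

.seq_codes <- function(s) {
  match(strsplit(toupper(s), "", fixed = FALSE)[[1L]], .BASES)
}

.revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# Window scores on one strand: sum over valid windows of the TRAP
# occupancy 1 / (1 + exp(E/lambda - lnR0)), E = log-odds mismatch energy
# versus the best-matching word. Windows containing N contribute 0.
.strand_affinity <- function(code, logp, best_total, lambda_trap, ln_r0) {
  L <- ncol(logp)
  n <- length(code)
  nw <- n - L + 1L
  if (nw < 1L) return(0)
  isna <- is.na(code)
  code0 <- ifelse(isna, 1L, code)
  scores <- numeric(nw)
  for (j in seq_len(L))
    scores <- scores + logp[cbind(code0[j:(j + nw - 1L)], j)]
  cs <- c(0, cumsum(isna))
  bad <- (cs[(L + 1L):(n + 1L)] - cs[1L:nw]) > 0
  energy <- best_total - scores  # >= 0
  aff <- 1 / (1 + exp(energy / lambda_trap - ln_r0))
  aff[bad] <- 0
  sum(aff)
}

#' Aggregate biophysical binding affinity of a TF over a sequence
#'
#' Sums, over all motif-length windows on both strands, the occupancy
#' probability `1 / (1 + exp(E_w / lambda - ln R0))`, where `E_w` is the
#' log-odds mismatch energy of window `w` relative to the PWM's best match.
#' Windows containing `N` contribute zero. Defaults follow the biophysical
#' affinity model's published parameterisation: `lambda = 0.7` and
#' `ln R0 = 0.584 * L - 5.66` for a motif of length `L`.
#'
#' @param sequence Single DNA string over A/C/G/T/N (or a
#'   [Biostrings::DNAString]).
#' @param pwm A `Pwm` object.
#' @param lambda_trap Energy scale; default 0.7.
#' @param ln_r0 log of the R0 prefactor; default `0.584 * L - 5.66`.
#' @return Nonnegative scalar affinity.
#' @examples
#' p <- new_pwm("TF1", matrix(c(10, 0, 0, 0, 0, 0, 0, 10), nrow = 4))
#' trap_affinity("ATATAT", p)
#' @export
trap_affinity <- function(sequence, pwm, lambda_trap = 0.7, ln_r0 = NULL) {
  if (methods::is(sequence, "DNAString") ||
      methods::is(sequence, "XStringSet"))
    sequence <- as.character(sequence)
  stopifnot(inherits(pwm, "Pwm"), is.character(sequence),
            length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  L <- pwm$length
  if (is.null(ln_r0)) ln_r0 <- 0.584 * L - 5.66
  if (nchar(sequence) < L) {
    warning("sequence shorter than motif; affinity 0")
    return(0)
  }
  logp <- log(pwm$prob)
  best_total <- sum(apply(logp, 2L, max))
  fwd <- .strand_affinity(.seq_codes(sequence), logp, best_total,
                          lambda_trap, ln_r0)
  rev <- .strand_affinity(.seq_codes(.revcomp(sequence)), logp, best_total,
                          lambda_trap, ln_r0)
  fwd + rev
}
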