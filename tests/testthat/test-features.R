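make_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("static features honour shape, determinism and truncation", {
  withr::with_seed(1, {
    chr <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  })
  genome <- make_genome(c(chr1 = chr))
  pwms <- list(new_pwm("TF1", matrix(c(9, 1, 1, 1, 1, 9, 1, 1), 4, 2)),
               new_pwm("TF2", matrix(c(1, 1, 9, 1, 1, 1, 1, 9), 4, 2)))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(2000L, 2000L, 100L), strand = "+")
  fm <- build_static_features(genes, genome, pwms, half_window = 500L)
  expect_s3_class(fm, "FeatureMatrix")
  expect_equal(dim(fm), c(3L, 2L))
  expect_identical(fm$flavour, "static")
  # identical windows -> identical rows
  expect_equal(fm$values["g1", ], fm$values["g2", ])
  # truncation at chromosome start equals the substring oracle
  sub <- substr(chr, 1, 600)  # [0,600) for tss 100, half 500
  expect_equal(unname(fm$values["g3", "TF1"]),
               oracle_trap(sub, pwms[[1]]), tolerance = 1e-10)
  expect_true(all(fm$values >= 0))
})

test_that("static features drop missing chromosomes and reject no PWMs", {
  genome <- make_genome(c(chr1 = strrep("ACGT", 500)))
  pwms <- list(new_pwm("TF1", matrix(1:8, 4, 2)))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chrZ"),
                      tss = c(500L, 500L), strand = "+")
  expect_warning(fm <- build_static_features(genes, genome, pwms,
                                             half_window = 100L),
                 "missing chromosome")
  expect_equal(rownames(fm$values), "g1")
  expect_error(build_static_features(genes[1, ], genome, list()), "PWM")
})

test_that("strand symmetry: reverse-complemented genome reproduces rows", {
  withr::with_seed(3, {
    chr <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    pwms <- list(new_pwm("TF1", matrix(runif(4 * 5, 0, 10), 4, 5)))
  })
  len <- nchar(chr)
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(chr, "")[[1]])),
              collapse = "")
  tss <- 1000L; half <- 200L
  g_fwd <- data.frame(gene_id = "g", chrom = "c", tss = tss, strand = "+")
  # the window [tss-half, tss+half) maps to [len-tss-half, len-tss+half)
  g_rev <- data.frame(gene_id = "g", chrom = "c", tss = len - tss,
                      strand = "-")
  f1 <- build_static_features(g_fwd, make_genome(c(c = chr)), pwms,
                              half_window = half)
  f2 <- build_static_features(g_rev, make_genome(c(c = rc)), pwms,
                              half_window = half)
  expect_equal(f1$values, f2$values, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("decay_weight closed form and monotonicity", {
  expect_equal(decay_weight(0, 5000), 1)
  expect_equal(decay_weight(5000, 5000), exp(-1))
  d <- sort(runif(10, 0, 2e4))
  expect_true(all(diff(decay_weight(d, 5000)) < 0))
  expect_error(decay_weight(-1, 5000), "nonnegative")
  expect_error(decay_weight(10, 0), "positive")
})

test_that("dynamic features match the brute-force overlap/decay oracle", {
  withr::with_seed(11, {
    chr <- paste(sample(c("A", "C", "G", "T"), 60000, TRUE), collapse = "")
    pwms <- list(new_pwm("TF1", matrix(runif(4 * 4, 0, 10), 4, 4)),
                 new_pwm("TF2", matrix(runif(4 * 4, 0, 10), 4, 4)))
    ps <- sample(0:59000, 25)
  })
  genome <- make_genome(c(chr1 = chr))
  peaks <- data.frame(chrom = "chr1", start = ps, end = ps + 400L,
                      signal = seq(1, 25) / 3)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(30000L, 5000L), strand = "+")
  half <- 25000L; d0 <- 5000
  fm <- build_dynamic_features(genes, genome, pwms, peaks,
                               half_window = half, d0 = d0)
  expect_identical(fm$flavour, "dynamic")
  ov <- oracle_overlaps(pmax(0, genes$tss - half), genes$tss + half,
                        peaks$start, peaks$end)
  for (g in 1:2) {
    idx <- which(ov[g, ])
    centres <- floor((peaks$start + peaks$end) / 2)
    w <- exp(-abs(genes$tss[g] - centres[idx]) / d0)
    for (t in 1:2) {
      aff <- vapply(idx, function(i) oracle_trap(
        substr(chr, peaks$start[i] + 1, peaks$end[i]), pwms[[t]]), 0)
      expect_equal(unname(fm$values[g, t]), sum(aff * w),
                   tolerance = 1e-8)
    }
    expect_equal(unname(fm$values[g, "Peak_Counts"]), length(idx))
    expect_equal(unname(fm$values[g, "Peak_Signal"]),
                 sum(peaks$signal[idx]))
    expect_equal(unname(fm$values[g, "Peak_Length"]),
                 sum(pmin(genes$tss[g] + half, peaks$end[idx]) -
                       pmax(max(0, genes$tss[g] - half),
                            peaks$start[idx])))
  }
})

test_that("dynamic features: zero-overlap gene and TSS-centred peak", {
  genome <- make_genome(c(chr1 = strrep("ACGT", 30000)))
  pwm <- list(new_pwm("TF1", matrix(c(5, 1, 1, 1, 1, 5, 1, 1), 4, 2)))
  peaks <- data.frame(chrom = "chr1", start = 49900L, end = 50100L,
                      signal = 2)
  genes <- data.frame(gene_id = c("far", "at"), chrom = "chr1",
                      tss = c(110000L, 50000L), strand = "+")
  fm <- build_dynamic_features(genes, genome, pwm, peaks)
  expect_equal(unname(fm$values["far", ]), rep(0, 4))
  # peak centred exactly at the TSS: decay weight 1
  chr <- as.character(genome[[1]])
  expect_equal(unname(fm$values["at", "TF1"]),
               oracle_trap(substr(chr, 49901, 50100), pwm[[1]]),
               tolerance = 1e-10)
  expect_error(build_dynamic_features(genes, genome, pwm,
                                      peaks[, 1:3]), "signal")
})

test_that("chipseq features use half-open overlap and match the oracle", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:4), chrom = "chr1",
                      tss = c(2000L, 6000L, 10000L, 14000L), strand = "+")
  # boundary: window of g1 is [500, 3500); a peak ending at 500 does not
  # overlap, a peak sharing exactly base 500 does
  tf_peaks <- list(
    TFa = data.frame(chrom = "chr1", start = c(0L, 400L), end = c(500L, 501L),
                     count = c(7L, 3L)))
  fm <- build_chipseq_features(genes, tf_peaks, half_window = 1500L)
  expect_identical(fm$flavour, "chipseq")
  expect_equal(unname(fm$values["g1", "TFa"]), 3)
  # random fixture vs exhaustive pairwise oracle
  withr::with_seed(5, {
    pk <- data.frame(chrom = "chr1",
                     start = sample(0:15000, 50), stringsAsFactors = FALSE)
    pk$end <- pk$start + sample(50:500, 50, TRUE)
    pk$count <- sample(0:30, 50, TRUE)
  })
  fm2 <- build_chipseq_features(genes, list(TFa = pk, TFb = pk[1:5, ]),
                                half_window = 1500L)
  ov <- oracle_overlaps(genes$tss - 1500, genes$tss + 1500,
                        pk$start, pk$end)
  expect_equal(unname(fm2$values[, "TFa"]),
               vapply(1:4, function(g) sum(pk$count[ov[g, ]]), 0))
  expect_warning(
    fm3 <- build_chipseq_features(genes, list(TFa = pk,
                                              none = pk[0, ])),
    "no peaks")
  expect_equal(unname(fm3$values[, "none"]), rep(0, 4))
})
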