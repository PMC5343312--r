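snpGenome <- function(seed = 41L, motif = "TTTCACTTTC", at = 2000L,
                      segLen = 5000L) {
  sp <- syntheticSpec(seed = seed,
    segments = data.frame(name = "s", length = segLen),
    plantedMotifs = data.frame(segment = "s", pos = at, strand = "+",
                               name = "irf", seq = motif))
  generateGenome(sp)$genome
}

test_that("context extraction substitutes the center base only", {
  genome <- snpGenome()
  snp <- list(chrom = "s", pos = 2004L, ref = "A", alt = "G")
  ctx <- extractContext(snp, genome)
  expect_equal(nchar(ctx$ref), 101L)
  expect_equal(ctx$offset, 51L)
  expect_identical(substr(ctx$ref, 51, 51), "A")
  expect_identical(substr(ctx$var, 51, 51), "G")
  diffs <- which(strsplit(ctx$ref, "")[[1]] != strsplit(ctx$var, "")[[1]])
  expect_identical(diffs, 51L)
  ## truncation at the segment start: 10 bp left flank -> 61 bp context
  snpEdge <- list(chrom = "s", pos = 10L, ref = substr(as.character(
    genome[["s"]]), 11, 11), alt = "C")
  if (snpEdge$ref == "C") snpEdge$alt <- "G"
  ctxE <- extractContext(snpEdge, genome)
  expect_equal(nchar(ctxE$ref), 61L)
  expect_equal(ctxE$offset, 11L)
  expect_equal(ctxE$start0, 0L)
  ## declared ref disagreeing with the genome warns but proceeds
  expect_warning(extractContext(list(chrom = "s", pos = 2004L, ref = "C",
                                     alt = "G"), genome), "declared ref")
  expect_error(extractContext(list(chrom = "s", pos = 2004L, ref = "A",
                                   alt = "N"), genome), "ACGT")
})

test_that("allele scoring classifies gain, loss, neutral and null", {
  pwm <- sharpPwm("TTTCACTTTC", hi = 97, lo = 1, name = "IRF1_synthetic")
  bg <- uniformBackground()
  genome <- snpGenome()
  ## loss: consensus base 5 (A) mutated away
  ctx <- extractContext(list(chrom = "s", pos = 2004L, ref = "A", alt = "G"),
                        genome)
  eff <- scoreAllelePair(ctx$ref, ctx$var, ctx$offset, pwm, bg)
  expect_identical(eff$verdict, "loss")
  expect_gt(eff$lr_ref, 500)
  expect_lt(eff$fold_change, 1 / 1.5)
  ## gain is the exact mirror (ref/alt swapped)
  swapped <- scoreAllelePair(ctx$var, ctx$ref, ctx$offset, pwm, bg)
  expect_identical(swapped$verdict, "gain")
  if (eff$lr_var > 0)
    expect_equal(swapped$fold_change, 1 / eff$fold_change, tolerance = 1e-9)
  ## self-comparison is neutral with fold 1
  self <- scoreAllelePair(ctx$ref, ctx$ref, ctx$offset, pwm, bg)
  expect_identical(self$verdict, "neutral")
  expect_equal(self$fold_change, 1)
  ## null_both far from any motif
  ctxFar <- extractContext(list(chrom = "s", pos = 4000L,
                                ref = substr(as.character(genome[["s"]]),
                                             4001, 4001),
                                alt = setdiff(c("A", "C", "G", "T"),
                                              substr(as.character(
                                                genome[["s"]]), 4001, 4001))[1]),
                           genome)
  far <- scoreAllelePair(ctxFar$ref, ctxFar$var, ctxFar$offset, pwm, bg)
  expect_identical(far$verdict, "null_both")
  expect_equal(far$lr_ref, 0)
  expect_true(is.na(far$fold_change))
  ## gain from a NULL reference: two mismatches restored by the variant
  broken <- sub("TTTCACTTTC", "TTTCGCTTGC", ctx$ref, fixed = TRUE)
  fixedOne <- sub("TTTCGCTTGC", "TTTCACTTGC", broken, fixed = TRUE)
  gainNull <- scoreAllelePair(broken, fixedOne, ctx$offset, pwm, bg)
  expect_identical(gainNull$verdict, "gain")
  expect_equal(gainNull$lr_ref, 0)
  expect_true(is.na(gainNull$fold_change))
  ## motif longer than the context errors
  expect_error(scoreAllelePair("ACGT", "ACGA", 2L, pwm, bg), "longer")
})

test_that("fold change matches a brute-force overlapping-window oracle", {
  set.seed(19)
  pwm <- buildPwm(matrix(rpois(24, 12) + 1, 4, 6), pseudocount = 0.5,
                  name = "toy6")
  bg <- fitBackground(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                            collapse = ""), k = 1L)
  bases <- c("A", "C", "G", "T")
  bestOverlapping <- function(seq, offset) {
    L <- 6L
    best <- 0
    for (i in max(1, offset - L + 1):min(nchar(seq) - L + 1, offset)) {
      win <- substr(seq, i, i + L - 1)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      for (w in c(win, rc)) {
        lr <- lrOracle(w, pwm, bg)
        if (lr > 500 && lr > best) best <- lr
      }
    }
    best
  }
  for (rep in 1:10) {
    s <- paste(sample(bases, 30, TRUE), collapse = "")
    offset <- 15L
    alt <- sample(setdiff(bases, substr(s, offset, offset)), 1)
    v <- s; substr(v, offset, offset) <- alt
    eff <- scoreAllelePair(s, v, offset, pwm, bg, lrMin = 500)
    expect_equal(eff$lr_ref, bestOverlapping(s, offset), tolerance = 1e-9)
    expect_equal(eff$lr_var, bestOverlapping(v, offset), tolerance = 1e-9)
  }
})

test_that("verdicts are stable to lr_min perturbation for clear cases", {
  pwm <- sharpPwm("TTTCACTTTC", hi = 97, lo = 1)
  bg <- uniformBackground()
  genome <- snpGenome()
  ctx <- extractContext(list(chrom = "s", pos = 2004L, ref = "A", alt = "G"),
                        genome)
  for (lrMin in c(200, 500, 1200))
    expect_identical(scoreAllelePair(ctx$ref, ctx$var, ctx$offset, pwm, bg,
                                     lrMin = lrMin)$verdict, "loss")
})

test_that("the SNP screen filters by peak then motif and counts stages", {
  pwm <- sharpPwm("TTTCACTTTC", hi = 97, lo = 1, name = "IRF1_synthetic")
  bg <- uniformBackground()
  genome <- snpGenome()
  peaks <- GRanges("s", IRanges(1801, 2600), tf = "IRF1", condition = "induced")
  hits <- scanMotifs(genome, pwm, bg)
  expect_gte(length(hits), 1L)
  snps <- data.frame(
    id = c("in_motif", "in_peak_only", "outside"),
    chrom = "s", pos = c(2004L, 2300L, 4000L),
    ref = c("A",
            substr(as.character(genome[["s"]]), 2301, 2301),
            substr(as.character(genome[["s"]]), 4001, 4001)),
    alt = "N")
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  snps$alt <- vapply(snps$ref, other, character(1))
  snps$alt[1] <- "G"
  scr <- screenSnps(snps, peaks, hits, genome, list(IRF1_synthetic = pwm), bg)
  expect_equal(unname(scr$counts), c(3L, 2L, 1L, 1L))
  expect_true(all(diff(unname(scr$counts)) <= 0))  # monotone filter
  expect_identical(scr$effects$snp_id, "in_motif")
  expect_identical(scr$effects$verdict, "loss")
  ## empty input short-circuits
  none <- screenSnps(snps[0, ], peaks, hits, genome,
                     list(IRF1_synthetic = pwm), bg)
  expect_equal(unname(none$counts), rep(0L, 4L))
})

test_that("planted disruptive SNPs in the default study are all recovered", {
  spec <- defaultSyntheticSpec(seed = 5L)
  g <- generateGenome(spec)
  pwms <- loadExamplePwms()
  bg <- fitBackground(g$genome, k = 3L)
  snps <- spec@plantedSnps
  names(snps)[names(snps) == "segment"] <- "chrom"
  ## score the three motif-overlapping SNPs directly against ground truth
  expectVerdict <- c(snp_loss_irf1 = "loss", snp_gain_irf1 = "gain",
                     snp_loss_stat1 = "loss")
  pwmFor <- c(snp_loss_irf1 = "IRF1_synthetic",
              snp_gain_irf1 = "IRF1_synthetic",
              snp_loss_stat1 = "STAT1_synthetic")
  for (id in names(expectVerdict)) {
    s <- snps[snps$id == id, ]
    ctx <- extractContext(s, g$genome)
    eff <- scoreAllelePair(ctx$ref, ctx$var, ctx$offset, pwms[[pwmFor[[id]]]],
                           bg)
    expect_identical(eff$verdict, unname(expectVerdict[id]), label = id)
    expect_true(is.na(eff$fold_change) ||
                  abs(log(eff$fold_change)) >= log(1.5), label = id)
  }
})
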