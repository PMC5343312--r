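test_that("buildPwm applies pseudo-counts per cell", {
  counts <- rbind(A = c(10, 5, 0, 1), C = c(0, 5, 0, 1),
                  G = c(0, 5, 0, 1), T = c(0, 5, 40, 1))
  pwm <- buildPwm(counts, pseudocount = 0.5, name = "toy")
  probs <- pwmProbs(pwm)
  expect_equal(unname(probs["A", 1]), 10.5 / 12, tolerance = 1e-12)
  expect_equal(unname(probs["C", 1]), 0.5 / 12, tolerance = 1e-12)
  expect_equal(unname(probs[, 2]), rep(0.25, 4))  # all-equal counts -> uniform
  expect_equal(colSums(probs), rep(1, 4), ignore_attr = TRUE)
  expect_error(buildPwm(counts, pseudocount = 0), "pseudocount")
  expect_error(buildPwm(counts[, 1:3], 0.5), "length")
})

test_that("JASPAR text PFMs parse into the bundled PWMs", {
  pwms <- loadExamplePwms()
  expect_named(pwms, c("STAT1_synthetic", "IRF1_synthetic"))
  expect_equal(motifLength(pwms$STAT1_synthetic), 9L)
  expect_equal(motifLength(pwms$IRF1_synthetic), 10L)
  ## consensus of the IRF-E-like matrix
  probs <- pwmProbs(pwms$IRF1_synthetic)
  cons <- paste(rownames(probs)[apply(probs, 2, which.max)], collapse = "")
  expect_identical(cons, "TTTCACTTTC")
  ## writer-free round trip on a temp file in both bracket styles
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">m1 test", "A 1 2 3 4", "C 4 3 2 1", "G 0 0 0 0",
               "T 5 5 5 5"), f)
  parsed <- readJasparPfm(f)
  expect_identical(parsed$name, "m1")
  expect_equal(parsed$counts["T", ], rep(5, 4), ignore_attr = TRUE)
})

test_that("background fitting matches hand counts with add-one smoothing", {
  bg0 <- fitBackground("ACGTACGT", k = 0L)
  expect_equal(unname(bg0@stationary), rep(0.25, 4))
  ## k=1 on AAAC without reverse complement: A->A twice, A->C once
  bg1 <- fitBackground("AAAC", k = 1L, addRevComp = FALSE)
  expect_equal(bg1@cond["A", "A"], 3 / 7, tolerance = 1e-12)
  expect_equal(bg1@cond["A", "C"], 2 / 7, tolerance = 1e-12)
  expect_equal(bg1@cond["A", "G"], 1 / 7, tolerance = 1e-12)
  expect_equal(bg1@cond["C", "A"], 0.25, tolerance = 1e-12)  # unseen context
  ## k=3 on short input: all 64 contexts defined and normalized
  bg3 <- fitBackground(paste(rep("ACGT", 25), collapse = ""), k = 3L)
  expect_equal(nrow(bg3@cond), 64L)
  expect_equal(rowSums(bg3@cond), rep(1, 64), ignore_attr = TRUE)
  expect_error(fitBackground(character(0)), "no training sequence")
})

test_that("uniform PWM on uniform background gives LR 1 and no hits", {
  pwm <- buildPwm(matrix(1, 4, 6), pseudocount = 0.5, name = "flat")
  bg <- uniformBackground()
  hits <- scanMotifs("ACGTACGTACGTACGT", pwm, bg, lrMin = 1.001)
  expect_length(hits, 0L)
  all <- scanMotifs("ACGTACGTACGTACGT", pwm, bg, lrMin = 0.5,
                    bothStrands = FALSE)
  expect_equal(all$lr, rep(1, 11), tolerance = 1e-9)
})

test_that("scan LRs match the term-by-term oracle over all 4^6 hexamers", {
  set.seed(31)
  pwm <- buildPwm(matrix(rpois(24, 20), 4, 6), pseudocount = 0.5, name = "r")
  bg <- fitBackground(paste(sample(c("A", "C", "G", "T"), 3000, TRUE,
                                   prob = c(0.3, 0.2, 0.2, 0.3)),
                            collapse = ""), k = 2L)
  bases <- c("A", "C", "G", "T")
  hexamers <- apply(do.call(expand.grid, rep(list(bases), 6)), 1, paste,
                    collapse = "")
  ## scan each hexamer embedded in one long sequence at stride 6: windows
  ## are self-contained so flanking content cannot change the LR
  concat <- paste(hexamers, collapse = "")
  hits <- scanMotifs(concat, pwm, bg, lrMin = 0, bothStrands = FALSE)
  atStride <- hits[(start(hits) - 1L) %% 6L == 0L]
  expect_length(atStride, 4096L)
  oracle <- vapply(hexamers, lrOracle, numeric(1), pwm = pwm, background = bg)
  got <- atStride$lr[match(seq(1L, by = 6L, length.out = 4096L),
                           start(atStride))]
  expect_equal(got, unname(oracle), tolerance = 1e-9)
})

test_that("a sharp consensus clears the LR > 500 cutoff", {
  pwm <- sharpPwm("TTTCACTTTC", hi = 97, lo = 1)
  bg <- uniformBackground()
  seq <- paste0("ACGTGGCCAA", "TTTCACTTTC", "AACCGGTTAC")
  hits <- scanMotifs(seq, pwm, bg)
  expect_length(hits, 1L)
  expect_equal(start(hits), 11L)
  expect_gt(hits$lr, 500)
  ## closed form: (p_hi / 0.25)^L with smoothed probabilities
  pHi <- (97 + 0.5) / (100 + 2)
  expect_equal(hits$lr, (pHi / 0.25)^10, tolerance = 1e-6)
})

test_that("strand handling mirrors hits with identical LRs", {
  set.seed(17)
  pwm <- buildPwm(matrix(rpois(40, 15) + 1, 4, 10), pseudocount = 0.5,
                  name = "asym")
  bg <- fitBackground(paste(sample(c("A", "C", "G", "T"), 4000, TRUE,
                                   prob = c(0.35, 0.15, 0.2, 0.3)),
                            collapse = ""), k = 3L)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scanMotifs(s, pwm, bg, lrMin = 0)
  rev <- scanMotifs(rc, pwm, bg, lrMin = 0)
  ## a hit spanning [i, j] on s maps to a hit at 200 - j + 1 on the rc,
  ## with the strand flipped and the LR unchanged
  expected <- paste(200L - end(fwd) + 1L,
                    ifelse(as.character(strand(fwd)) == "+", "-", "+"),
                    round(log(fwd$lr), 9))
  observed <- paste(start(rev), as.character(strand(rev)),
                    round(log(rev$lr), 9))
  expect_setequal(expected, observed)
})

test_that("windows containing N are skipped and tallied", {
  pwm <- sharpPwm("TTTCAC", hi = 97, lo = 1)
  bg <- uniformBackground()
  hits <- scanMotifs("AANGGTTTCACGG", pwm, bg, lrMin = 0, bothStrands = FALSE)
  expect_equal(S4Vectors::metadata(hits)$n_skipped, 3L)
  expect_false(any(start(hits) <= 3L))
  ## shorter than the motif: no hits
  expect_length(scanMotifs("ACG", pwm, bg), 0L)
})

test_that("planted consensus motifs are recovered without off-target hits", {
  ## a 12-mer makes chance occurrences negligible; hi = 99997 keeps even
  ## single-mismatch windows below LR 500
  cons <- "TTCCGGGAATCC"
  pwm <- sharpPwm(cons, hi = 99997, lo = 1, pseudocount = 0.5)
  for (seed in 1:20) {
    sp <- syntheticSpec(seed = seed,
      segments = data.frame(name = "s", length = 10000L),
      plantedMotifs = data.frame(segment = "s", pos = c(3000L, 7000L),
                                 strand = c("+", "-"), name = "gas",
                                 seq = cons))
    g <- generateGenome(sp)
    bg <- fitBackground(g$genome, k = 0L)
    hits <- scanMotifs(g$genome, pwm, bg, lrMin = 500)
    expect_setequal(start(hits), c(3001L, 7001L))
  }
})

test_that("motif frequency comparison uses an exact two-proportion test", {
  pwm <- sharpPwm("TTTCACTTTC", hi = 97, lo = 1)
  bg <- uniformBackground()
  set.seed(23)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  withM <- Biostrings::DNAStringSet(vapply(1:30, function(i)
    paste0(rand(20), "TTTCACTTTC", rand(20)), character(1)))
  without <- Biostrings::DNAStringSet(vapply(1:30, function(i) rand(50),
                                             character(1)))
  cmp <- motifFrequencyCompare(withM, without, pwm, bg)
  expect_equal(cmp$pct_peaks_with_motif, 100)
  expect_equal(cmp$p_value,
               twoProportionOracle(cmp$n_peaks_with_motif, 30,
                                   cmp$n_random_with_motif, 30),
               tolerance = 1e-10)
  ## identical sets: p = 1, not significant
  same <- motifFrequencyCompare(withM, withM, pwm, bg)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  expect_error(motifFrequencyCompare(withM[0], without, pwm, bg), "non-empty")
})

test_that("the 60/100 vs 10/100 case matches the exact oracle", {
  ## drive the proportion test directly through sequences with/without motif
  pwm <- sharpPwm("TTTCACTTTC", hi = 97, lo = 1)
  bg <- uniformBackground()
  spacer <- function() paste(rep("ACGG", 10), collapse = "")
  mk <- function(nWith, nTotal) {
    s <- c(replicate(nWith, paste0(spacer(), "TTTCACTTTC", spacer())),
           replicate(nTotal - nWith, spacer()))
    Biostrings::DNAStringSet(s)
  }
  cmp <- motifFrequencyCompare(mk(60, 100), mk(10, 100), pwm, bg)
  expect_equal(cmp$n_peaks_with_motif, 60L)
  expect_equal(cmp$n_random_with_motif, 10L)
  expect_equal(cmp$p_value, twoProportionOracle(60, 100, 10, 100),
               tolerance = 1e-10)
  expect_true(cmp$significant)  # p far below 5e-5
  expect_identical(cmp$method, "fisher-exact")
})
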