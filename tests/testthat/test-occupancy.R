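mkGenes <- function(pos, ids = sprintf("g%02d", seq_along(pos)),
                    class = "other", chrom = "chrT", pseudo = FALSE) {
  GRanges(chrom, IRanges(pos, width = 1L), strand = "+", gene_id = ids,
          class = class, known_isg = FALSE, pot_isg = FALSE,
          pseudogene = pseudo)
}

test_that("assignPeaks measures center-to-TSS distance with inclusive 5 kb", {
  genes <- mkGenes(100000L)
  pk <- function(center) GRanges("chrT", IRanges(center - 200L, center + 200L))
  onTss <- assignPeaks(pk(100000L), genes)
  expect_equal(onTss$distance, 0)
  expect_true(onTss$proximal)
  at5000 <- assignPeaks(pk(105000L), genes)
  expect_equal(at5000$distance, 5000)
  expect_true(at5000$proximal)          # inclusive boundary
  at5001 <- assignPeaks(pk(105001L), genes)
  expect_false(at5001$proximal)
  ## ties broken by smaller gene_id
  two <- mkGenes(c(99000L, 101000L), ids = c("gB", "gA"))
  tie <- assignPeaks(pk(100000L), two)
  expect_identical(tie$gene_id, "gA")
  ## peak on a chromosome without genes is unassigned
  lost <- assignPeaks(GRanges("chrX", IRanges(1, 400)), genes)
  expect_false(lost$assigned)
  expect_equal(lost$distance, Inf)
  ## pseudogenes excluded by default, included on request
  withPseudo <- c(mkGenes(100000L), mkGenes(100200L, ids = "pg1", pseudo = TRUE))
  expect_identical(assignPeaks(pk(100300L), withPseudo)$gene_id, "g01")
  expect_identical(assignPeaks(pk(100300L), withPseudo,
                               includePseudogenes = TRUE)$gene_id, "pg1")
})

test_that("buildLedger links by overlap or 500 bp gap and labels regions", {
  s1 <- GRanges("chrT", IRanges(101, 600))
  i1 <- GRanges("chrT", IRanges(551, 900))
  dual <- buildLedger(s1, i1)
  expect_length(dual, 1L)
  expect_identical(dual$label, "dual")
  expect_equal(start(dual), 101)
  expect_equal(end(dual), 900)
  ## gap 1100 > 500: two isolated regions
  apart <- buildLedger(GRanges("chrT", IRanges(1, 400)),
                       GRanges("chrT", IRanges(1501, 1900)))
  expect_identical(apart$label, c("isolated-STAT1", "isolated-IRF1"))
  ## gap exactly 500 links
  linked <- buildLedger(GRanges("chrT", IRanges(1, 400)),
                        GRanges("chrT", IRanges(901, 1300)))
  expect_identical(linked$label, "dual")
  ## strict-overlap mode separates them
  strict <- buildLedger(GRanges("chrT", IRanges(1, 400)),
                        GRanges("chrT", IRanges(901, 1300)), linkBp = 0L)
  expect_length(strict, 2L)
  ## singleton
  one <- buildLedger(GRanges("chrT", IRanges(1, 400)), GRanges())
  expect_identical(one$label, "isolated-STAT1")
})

test_that("ledger partitions peaks: each peak in exactly one region", {
  set.seed(5)
  st <- sort(GRanges("chrT", IRanges(sample(1:500000, 60) * 10L, width = 400L)))
  ir <- sort(GRanges("chrT", IRanges(sample(1:500000, 90) * 10L, width = 400L)))
  led <- buildLedger(st, ir)
  expect_equal(sum(led$n_stat1), 60L)
  expect_equal(sum(led$n_irf1), 90L)
  expect_identical(unname(sort(unlist(led$stat1_peaks))), 1:60)
  expect_identical(unname(sort(unlist(led$irf1_peaks))), 1:90)
  counts <- table(factor(led$label, c("isolated-STAT1", "isolated-IRF1", "dual")))
  expect_equal(sum(counts), length(led))
  ## dual iff both lists non-empty
  expect_true(all((led$n_stat1 > 0 & led$n_irf1 > 0) == (led$label == "dual")))
})

test_that("co-occupancy summary reproduces the printed ledger decomposition", {
  pks <- printedLedgerPeaks()
  led <- buildLedger(pks$stat1, pks$irf1)
  expect_length(led, 230L)
  sm <- summarizeCooccupancy(led)
  expect_equal(sm$n_isolated_stat1, 36L)
  expect_equal(sm$n_isolated_irf1, 140L)
  expect_equal(sm$n_dual, 54L)
  expect_equal(sm$n_stat1_peaks, 92L)
  expect_equal(sm$n_irf1_peaks, 196L)
  expect_equal(sm$isolated_stat1_pct, 16)
  expect_equal(sm$isolated_irf1_pct, 61)
  expect_equal(sm$dual_pct, 23)
  expect_equal(sm$dual_share_stat1_pct, 59)
  expect_equal(sm$dual_share_irf1_pct, 28)
  empty <- summarizeCooccupancy(buildLedger(GRanges(), GRanges()))
  expect_equal(empty$n_regions, 0L)
  expect_equal(empty$dual_pct, 0)
})

test_that("random sites are length-matched, peak-free and deterministic", {
  set.seed(3)
  segments <- GRanges(c("sA", "sB"), IRanges(1, c(400000L, 200000L)))
  peaks <- suppressWarnings(
    c(GRanges("sA", IRanges(sample(1:390000, 30), width = sample(200:900, 30, TRUE))),
      GRanges("sB", IRanges(sample(1:190000, 10), width = sample(200:900, 10, TRUE)))))
  r1 <- sampleRandomSites(peaks, segments, seed = 77L)
  r2 <- sampleRandomSites(peaks, segments, seed = 77L)
  expect_identical(r1, r2)
  expect_length(r1, length(peaks))
  expect_identical(sort(width(r1)), sort(width(peaks)))
  ov <- findOverlaps(r1, peaks)
  expect_length(ov, 0L)
  ## per-segment proportions track the real peaks as n grows
  rBig <- sampleRandomSites(peaks, segments, n = 10000L, seed = 78L)
  obs <- table(factor(as.character(seqnames(rBig)), c("sA", "sB")))
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = c(30, 10) / 40))
  expect_gt(chi$p.value, 0.01)
})

test_that("TER is 1 under self-comparison and matches a constructed ratio", {
  genes <- mkGenes(c(50000L, 150000L, 250000L, 350000L),
                   class = c("es-indISG", "resISG", "ls-IRG", "other"))
  pk <- function(centers) GRanges("chrT", IRanges(centers - 100L, centers + 99L))
  a <- assignPeaks(pk(c(50200L, 150300L, 250100L, 350050L)), genes)
  self <- computeTER(a, a)
  expect_true(all(self$ter[self$n_observed > 0] == 1))
  ## all TF sites proximal at one class; random uniform over four classes
  obs <- assignPeaks(pk(rep(50200L, 8)), genes)
  rnd <- assignPeaks(pk(c(50200L, 150300L, 250100L, 350050L)), genes)
  ter <- computeTER(obs, rnd)
  cell <- ter[ter$gene_class == "es-indISG" & ter$location == "proximal", ]
  expect_equal(cell$ter, 4)
  expect_true(cell$above_threshold)
  ## observed support without random support flags infinity
  rnd2 <- assignPeaks(pk(150300L), genes)
  ter2 <- computeTER(obs, rnd2)
  cell2 <- ter2[ter2$gene_class == "es-indISG" & ter2$location == "proximal", ]
  expect_identical(cell2$ter, Inf)
})

test_that("binding profiles anchor on the TSS and mark truncation missing", {
  segments <- GRanges("chrT", IRanges(1, 300000L))
  gene <- mkGenes(250000L)              # 50 kb from the segment end
  peak <- GRanges("chrT", IRanges(250150, 250350))  # center at TSS + 250
  bp <- bindingProfile(peak, gene, segments)
  prof <- bp$profile
  expect_equal(prof$mean_frequency[prof$window == 0], 1)
  expect_equal(sum(prof$mean_frequency, na.rm = TRUE), 1)
  ## windows beyond +50 kb are missing, not zero
  expect_true(all(is.na(prof$mean_frequency[prof$window > 50])))
  expect_true(all(prof$n_genes[prof$window > 50] == 0))
  expect_true(all(prof$mean_frequency[prof$window >= -199 & prof$window < 50]
                  >= 0))
  ## averaging over two genes halves the frequency
  genes2 <- mkGenes(c(150000L, 250000L))
  bp2 <- bindingProfile(peak, genes2, segments)
  w0 <- bp2$profile[bp2$profile$window == 0, ]
  expect_equal(w0$mean_frequency, 0.5)
  expect_equal(w0$n_genes, 2L)
  ## minus-strand gene flips the offset sign
  gm <- mkGenes(250000L); strand(gm) <- "-"
  bpm <- bindingProfile(peak, gm, segments)
  hit <- bpm$profile$window[which(bpm$profile$mean_frequency > 0)]
  expect_equal(hit, 0)  # +250 rounds into window 0 on either strand
  peak2 <- GRanges("chrT", IRanges(251501, 251700))  # center +1600 -> window 2
  bpp <- bindingProfile(peak2, mkGenes(250000L), segments)
  bpm2 <- bindingProfile(peak2, gm, segments)
  expect_equal(bpp$profile$window[which(bpp$profile$mean_frequency > 0)], 2)
  expect_equal(bpm2$profile$window[which(bpm2$profile$mean_frequency > 0)], -2)
})

test_that("profile mass equals peak-gene incidences within range", {
  set.seed(9)
  segments <- GRanges("chrT", IRanges(1, 1000000L))
  genes <- mkGenes(sort(sample(300000:700000, 5)))
  peaks <- GRanges("chrT", IRanges(sort(sample(1:999000, 40)), width = 300L))
  bp <- bindingProfile(peaks, genes, segments)
  mass <- sum(bp$counts, na.rm = TRUE)
  centers <- mid(ranges(peaks))
  inc <- 0L
  for (g in start(genes)) {
    rel <- centers - g
    k <- floor((rel + 500) / 1000)
    inSeg <- (g + k * 1000 - 500) >= 1 & (g + k * 1000 + 499) <= 1000000
    inc <- inc + sum(abs(k) <= 200 & inSeg)
  }
  expect_equal(mass, inc)
})

test_that("segment statistics reproduce the printed per-segment table", {
  fx <- printedSegmentFixture()
  st <- segmentStats(fx$peaks, fx$genes, fx$segments)
  mhc <- st[st$segment == "MHC", ]
  expect_equal(mhc$n_irf1, 56L)
  expect_equal(mhc$n_stat1, 16L)
  expect_equal(mhc$irf1_stat1_ratio, 3.5)
  expect_equal(round(100 * mhc$irf1_proximal_frac_pseudo), 77)
  expect_equal(round(100 * mhc$irf1_proximal_frac), 46)  # 26/56 without pseudogenes
  overall <- st[st$segment == "overall", ]
  expect_equal(overall$n_genes, 375L)
  expect_equal(round(100 * overall$isg_frac), 25)
  expect_equal(overall$es_indisg_per_mb, 1.9)
  ## empty segment yields zeros and an undefined ratio
  st0 <- segmentStats(GRanges(tf = character(), condition = character()),
                      fx$genes, fx$segments)
  expect_true(all(is.na(st0$irf1_stat1_ratio)))
  expect_true(all(st0$n_irf1 == 0L))
})

test_that("basal/induced fractions match the printed peak counts", {
  sm <- basalInducedSummary(printedBasalInducedPeaks())
  expect_equal(sm$basal_pct_of_induced[sm$tf == "STAT1"], 2.2)
  expect_equal(sm$basal_pct_of_induced[sm$tf == "IRF1"], 14.3)
})
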