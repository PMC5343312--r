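## Fixture builders shared across tests. Everything is constructed in code;
## coordinates are chosen so region linkage (500 bp) behaves predictably.

library(GenomicRanges)

## A toy TilingExperiment from explicit chip/input matrices on a uniform
## probe grid (80 bp spacing, 50-mers on one chromosome).
toyExperiment <- function(chip, input, spacing = 80L, probeLen = 50L,
                          chrom = "chrT", normalized = TRUE) {
  n <- nrow(chip)
  probes <- GRanges(chrom, IRanges(start = spacing * (seq_len(n) - 1L) + 1L,
                                   width = probeLen))
  probes$probe_id <- sprintf("p%04d", seq_len(n))
  tilingExperiment(probes, cbind(chip, input),
                   channel = rep(c("chip", "input"),
                                 c(ncol(chip), ncol(input))),
                   replicate = c(seq_len(ncol(chip)), seq_len(ncol(input))),
                   tf = "STAT1", condition = "induced",
                   normalized = normalized)
}

## Reconstruction of the reported region ledger decomposition: 92 STAT1 and
## 196 IRF1 peaks arranged into 36 isolated-STAT1, 140 isolated-IRF1 and 54
## dual regions (two dual regions carry a second STAT1 peak, two a second
## IRF1 peak). Blocks are spaced far beyond the 500 bp linkage distance.
printedLedgerPeaks <- function() {
  block <- function(i) 1L + (i - 1L) * 5000L
  stat1 <- GRanges(); irf1 <- GRanges()
  ## 36 isolated STAT1 blocks
  b <- block(1:36)
  stat1 <- c(stat1, GRanges("chrT", IRanges(b, width = 400L)))
  ## 140 isolated IRF1 blocks
  b <- block(37:176)
  irf1 <- c(irf1, GRanges("chrT", IRanges(b, width = 400L)))
  ## 54 dual blocks: overlapping STAT1/IRF1 pair
  b <- block(177:230)
  stat1 <- c(stat1, GRanges("chrT", IRanges(b, width = 400L)))
  irf1 <- c(irf1, GRanges("chrT", IRanges(b + 200L, width = 400L)))
  ## extra peaks inside four dual blocks (within 500 bp linkage)
  stat1 <- c(stat1, GRanges("chrT", IRanges(block(177:178) + 800L, width = 300L)))
  irf1 <- c(irf1, GRanges("chrT", IRanges(block(179:180) + 800L, width = 300L)))
  list(stat1 = sort(stat1), irf1 = sort(irf1))
}

## Segment/gene/peak decomposition matching the printed per-segment table:
## an MHC-like 5 Mb segment with 56 IRF1 / 16 STAT1 sites of which 26 lie
## within 5 kb of gene TSSs and 17 within 5 kb of pseudogene TSSs, inside a
## 16 Mb study of 375 genes (95 known ISGs, 31 early strong induced).
printedSegmentFixture <- function() {
  segments <- GRanges(c("MHC", "rest"), IRanges(1L, c(5000000L, 11000000L)))
  ## genes: 100 on MHC, 275 on rest, spaced 30 kb
  mkGenes <- function(chrom, n, offset, prefix) {
    GRanges(chrom, IRanges(offset + 30000L * (seq_len(n) - 1L), width = 1L),
            strand = "+",
            gene_id = sprintf("%s%03d", prefix, seq_len(n)))
  }
  genes <- suppressWarnings(c(mkGenes("MHC", 100L, 20001L, "gM"),
                              mkGenes("rest", 275L, 20001L, "gR")))
  ## 95 known ISGs of which 31 es-indISG (12 of each on the MHC)
  cls <- rep("other", 375)
  cls[1:31] <- "es-indISG"          # 12 MHC (1:12), 19 rest via reorder below
  known <- rep(FALSE, 375)
  known[1:95] <- TRUE
  genes$class <- cls
  genes$known_isg <- known
  genes$pot_isg <- FALSE
  genes$pseudogene <- FALSE
  ## pseudogenes on the MHC, far (>5 kb) from real gene TSSs
  pseudo <- GRanges("MHC", IRanges(3000001L + 40000L * (0:19), width = 1L),
                    strand = "+",
                    gene_id = sprintf("pg%03d", 1:20), class = "other",
                    known_isg = FALSE, pot_isg = FALSE, pseudogene = TRUE)
  genes <- c(genes, pseudo)
  ## MHC peaks: 26 IRF1 at gene TSSs, 17 IRF1 at pseudogene TSSs, 13 remote,
  ## 16 STAT1 remote
  at <- function(chrom, pos, tf)
    GRanges(chrom, IRanges(pos, width = 400L), tf = tf, condition = "induced")
  irf1 <- c(at("MHC", start(genes)[1:26] + 300L, "IRF1"),
            at("MHC", start(pseudo)[1:17] + 300L, "IRF1"),
            at("MHC", 4000001L + 50000L * (0:12), "IRF1"))
  stat1 <- at("MHC", 4700001L + 18000L * (0:15), "STAT1")
  peaks <- sort(c(irf1, stat1))
  list(segments = segments, genes = sort(genes, ignore.strand = TRUE),
       peaks = peaks)
}

## Peak set with the reported basal/induced counts (2/92 STAT1, 28/196 IRF1).
printedBasalInducedPeaks <- function() {
  mk <- function(n, tf, condition, offset)
    GRanges("chrT", IRanges(offset + 2000L * (seq_len(n) - 1L), width = 400L),
            tf = tf, condition = condition)
  c(mk(2L, "STAT1", "basal", 1L), mk(92L, "STAT1", "induced", 10001L),
    mk(28L, "IRF1", "basal", 200001L), mk(196L, "IRF1", "induced", 280001L))
}

## Exhaustive one-sided rank-sum oracle: enumerates every assignment of the
## pooled values to the two groups and counts rank sums at least as large.
rankSumOracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  idx <- combn(length(pooled), n1)
  w <- sum(r[seq_len(n1)])
  count <- 0L
  for (j in seq_len(ncol(idx)))
    if (sum(r[idx[, j]]) >= w - 1e-9) count <- count + 1L
  count / ncol(idx)
}

## Term-by-term likelihood-ratio oracle matching the self-contained window
## background convention (first k positions from the stationary composition,
## later ones conditional on the preceding bases inside the window).
lrOracle <- function(seq, pwm, background) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(seq, "")[[1]]
  probs <- pwmProbs(pwm)
  L <- ncol(probs)
  stopifnot(length(s) == L)
  num <- 1
  for (j in seq_len(L)) num <- num * probs[s[j], j]
  k <- backgroundOrder(background)
  den <- 1
  for (j in seq_len(L)) {
    if (j <= k) den <- den * background@stationary[s[j]]
    else if (k == 0L) den <- den * background@stationary[s[j]]
    else {
      ctx <- paste(s[(j - k):(j - 1)], collapse = "")
      den <- den * background@cond[ctx, s[j]]
    }
  }
  num / den
}

## Two-sided Fisher oracle by direct hypergeometric enumeration.
twoProportionOracle <- function(x1, n1, x2, n2) {
  support <- max(0L, x1 + x2 - n2):min(n1, x1 + x2)
  dens <- dhyper(support, n1, n2, x1 + x2)
  sum(dens[dens <= dhyper(x1, n1, n2, x1 + x2) * (1 + 1e-7)])
}

## A sharp PWM whose consensus is the given sequence.
sharpPwm <- function(consensus, name = "sharp", hi = 88, lo = 4,
                     pseudocount = 0.5) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(consensus, "")[[1]]
  counts <- matrix(lo, 4L, length(s), dimnames = list(bases, NULL))
  counts[cbind(match(s, bases), seq_along(s))] <- hi
  buildPwm(counts, pseudocount = pseudocount, name = name)
}

## Uniform order-0 background.
uniformBackground <- function() {
  fitBackground(Biostrings::DNAStringSet(paste(rep("ACGT", 2500), collapse = "")),
                k = 0L)
}
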