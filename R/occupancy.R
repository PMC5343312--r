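## Occupancy statistics: nearest-gene assignment with the 5 kb
## proximal/distal rule, the isolated/dual region ledger, matched random-site
## sampling, TF enrichment ratios (TER), TSS-anchored binding profiles and
## per-segment summaries.

#' Assign peaks to their nearest gene
#'
#' Each peak is assigned to the gene (same chromosome) whose TSS is closest
#' to the peak center; distance is |center - TSS| and a peak is proximal
#' when the distance is at most \code{proximalBp} (inclusive). Ties are
#' broken by the lexicographically smaller \code{gene_id}. Pseudogenes are
#' excluded unless \code{includePseudogenes}. Peaks on a chromosome without
#' genes are flagged unassigned with infinite distance.
#'
#' @param peaks \link[GenomicRanges]{GRanges} of peaks.
#' @param genes GRanges of width-1 TSS positions with metadata columns
#'   \code{gene_id}, \code{class}, and optionally \code{pseudogene}.
#' @param proximalBp proximal cutoff in bp (default 5000, inclusive).
#' @param includePseudogenes include pseudogenes among assignment targets.
#' @return data.frame with one row per peak: \code{chrom}, \code{center},
#'   \code{gene_id}, \code{gene_class}, \code{distance}, \code{proximal},
#'   \code{assigned}.
#' @export
assignPeaks <- function(peaks, genes, proximalBp = 5000, includePseudogenes = FALSE) {
  if (!includePseudogenes && "pseudogene" %in% names(mcols(genes)))
    genes <- genes[!genes$pseudogene]
  n <- length(peaks)
  chrom <- as.character(seqnames(peaks))
  center <- floor((start(peaks) + end(peaks)) / 2)
  gchrom <- as.character(seqnames(genes))
  gid <- genes$gene_id
  gclass <- if ("class" %in% names(mcols(genes))) genes$class else
    rep(NA_character_, length(genes))
  out <- data.frame(chrom = chrom, center = center,
                    gene_id = NA_character_, gene_class = NA_character_,
                    distance = Inf, proximal = FALSE, assigned = FALSE)
  for (s in unique(chrom)) {
    pi <- which(chrom == s)
    gi <- which(gchrom == s)
    if (!length(gi)) next
    o <- gi[order(start(genes)[gi], gid[gi])]
    tss <- start(genes)[o]
    j <- findInterval(center[pi], tss)
    for (kk in seq_along(pi)) {
      p <- pi[kk]
      cand <- unique(pmin(pmax(c(j[kk], j[kk] + 1L), 1L), length(tss)))
      dmin <- min(abs(center[p] - tss[cand]))
      ## all equidistant genes (covers duplicated TSS positions), smallest id
      tied <- which(abs(center[p] - tss) == dmin)
      pick <- tied[order(gid[o[tied]])][1L]
      out$gene_id[p] <- gid[o[pick]]
      out$gene_class[p] <- gclass[o[pick]]
      out$distance[p] <- abs(center[p] - tss[pick])
      out$assigned[p] <- TRUE
    }
  }
  out$proximal <- out$assigned & out$distance <= proximalBp
  out
}

#' Build the isolated/dual region ledger
#'
#' Merges STAT1 and IRF1 peaks into discrete regions: two peaks belong to
#' the same region when their intervals overlap by at least 1 bp or lie
#' within \code{linkBp} of each other (connected components). Each region is
#' labeled \code{isolated-STAT1}, \code{isolated-IRF1} or \code{dual}
#' according to which TFs contribute peaks; every peak lands in exactly one
#' region.
#'
#' @param stat1Peaks,irf1Peaks GRanges of per-TF peaks.
#' @param linkBp linkage distance in bp (default 500, the merge window; use
#'   0 for strict overlap only).
#' @return GRanges of disjoint regions with metadata columns \code{label},
#'   \code{n_stat1}, \code{n_irf1}, and \code{stat1_peaks} /
#'   \code{irf1_peaks} (\link[IRanges]{IntegerList} of peak indices into the
#'   input vectors).
#' @export
buildLedger <- function(stat1Peaks, irf1Peaks, linkBp = 500L) {
  all <- c(granges(stat1Peaks), granges(irf1Peaks))
  regions <- reduce(all, min.gapwidth = linkBp + 1L)
  ovS <- findOverlaps(granges(stat1Peaks), regions, maxgap = 0L)
  ovI <- findOverlaps(granges(irf1Peaks), regions, maxgap = 0L)
  nS <- tabulate(S4Vectors::subjectHits(ovS), length(regions))
  nI <- tabulate(S4Vectors::subjectHits(ovI), length(regions))
  regions$label <- ifelse(nS > 0 & nI > 0, "dual",
                          ifelse(nS > 0, "isolated-STAT1", "isolated-IRF1"))
  regions$n_stat1 <- nS
  regions$n_irf1 <- nI
  regions$stat1_peaks <- IRanges::IntegerList(
    split(S4Vectors::queryHits(ovS),
          factor(S4Vectors::subjectHits(ovS), levels = seq_along(regions))))
  regions$irf1_peaks <- IRanges::IntegerList(
    split(S4Vectors::queryHits(ovI),
          factor(S4Vectors::subjectHits(ovI), levels = seq_along(regions))))
  regions
}

#' Summarize isolated/dual co-occupancy
#'
#' Counts regions by label and reports their shares of all regions, plus the
#' dual share of each TF's peaks (number of dual regions over the TF's peak
#' count — the arithmetic used in the reported ledgers). Percentages are
#' rounded to the nearest integer for reporting; raw fractions are retained.
#'
#' @param ledger GRanges from [buildLedger()].
#' @return list with \code{n_regions}, per-label counts and integer
#'   percentages, raw fractions, and \code{dual_share_stat1_pct} /
#'   \code{dual_share_irf1_pct}.
#' @export
summarizeCooccupancy <- function(ledger) {
  nReg <- length(ledger)
  cnt <- function(lab) if (nReg) sum(ledger$label == lab) else 0L
  nS <- cnt("isolated-STAT1"); nI <- cnt("isolated-IRF1"); nD <- cnt("dual")
  nStat1Peaks <- if (nReg) sum(ledger$n_stat1) else 0L
  nIrf1Peaks <- if (nReg) sum(ledger$n_irf1) else 0L
  pct <- function(a, b) if (b > 0) round(100 * a / b) else 0
  frac <- function(a, b) if (b > 0) a / b else 0
  list(n_regions = nReg,
       n_isolated_stat1 = nS, n_isolated_irf1 = nI, n_dual = nD,
       n_stat1_peaks = nStat1Peaks, n_irf1_peaks = nIrf1Peaks,
       isolated_stat1_pct = pct(nS, nReg),
       isolated_irf1_pct = pct(nI, nReg),
       dual_pct = pct(nD, nReg),
       isolated_stat1_frac = frac(nS, nReg),
       isolated_irf1_frac = frac(nI, nReg),
       dual_frac = frac(nD, nReg),
       dual_share_stat1_pct = pct(nD, nStat1Peaks),
       dual_share_irf1_pct = pct(nD, nIrf1Peaks),
       dual_share_stat1_frac = frac(nD, nStat1Peaks),
       dual_share_irf1_frac = frac(nD, nIrf1Peaks))
}

#' Sample matched random control sites
#'
#' Draws \code{n} intervals from the tiled segments, length-matched 1:1 to
#' the input peaks (cycled when \code{n} exceeds the peak count), with
#' per-segment counts allocated proportionally to the real per-segment peak
#' counts (largest-remainder rounding), and rejected until they overlap no
#' real peak. Reproducible for a fixed seed.
#'
#' @param peaks GRanges of real peaks (any TF).
#' @param segments GRanges covering the tiled segments.
#' @param n number of sites (default \code{length(peaks)}).
#' @param seed integer seed.
#' @param maxTries placement attempts per interval before giving up.
#' @return GRanges of \code{n} random sites, sorted.
#' @export
sampleRandomSites <- function(peaks, segments, n = length(peaks), seed,
                              maxTries = 10000L) {
  stopifnot(n >= 1L, length(peaks) >= 1L)
  segNames <- as.character(seqnames(segments))
  pkSeg <- as.character(seqnames(peaks))
  if (!all(pkSeg %in% segNames)) stop("segments must cover all peaks")
  cnt <- table(factor(pkSeg, levels = segNames))
  exact <- n * as.numeric(cnt) / sum(cnt)
  target <- floor(exact)
  rem <- n - sum(target)
  if (rem > 0) {
    o <- order(exact - target, decreasing = TRUE)
    target[o[seq_len(rem)]] <- target[o[seq_len(rem)]] + 1L
  }
  withSeed(seed, {
    out <- list()
    for (si in seq_along(segNames)) {
      k <- target[si]
      if (k == 0) next
      seg <- segments[si]
      widths <- width(peaks)[pkSeg == segNames[si]]
      if (!length(widths)) widths <- width(peaks)
      widths <- rep_len(widths[order(widths)], k)
      starts <- integer(k)
      segPeaks <- ranges(peaks[pkSeg == segNames[si]])
      for (j in seq_len(k)) {
        w <- widths[j]
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          st <- floor(runif(1, start(seg), end(seg) - w + 2))
          if (!length(segPeaks) ||
              !any(st <= end(segPeaks) & st + w - 1 >= start(segPeaks))) {
            starts[j] <- st; placed <- TRUE; break
          }
        }
        if (!placed)
          stop(sprintf("could not place a %d bp random site in segment %s",
                       w, segNames[si]))
      }
      out[[segNames[si]]] <- GRanges(segNames[si],
                                     IRanges(starts, width = widths))
    }
    sites <- sort(suppressWarnings(do.call(c, unname(out))))
    suppressWarnings(seqlevels(sites) <- seqlevels(segments))
    sites
  })
}

#' TF enrichment ratio against random sites
#'
#' For each (gene class, proximal/distal) cell, the observed percentage of
#' TF sites whose nearest gene is in the class at that location is divided
#' by the same percentage for matched random sites (TER). Cells with random
#' support 0 but observed support > 0 are flagged infinite rather than
#' substituted.
#'
#' @param assignedPeaks,assignedRandom data.frames from [assignPeaks()] run
#'   against the same gene set.
#' @param classes gene classes to tabulate (default: classes present in
#'   either assignment).
#' @param terThreshold the minimum-enrichment flag threshold (default 2).
#' @return data.frame with columns \code{gene_class}, \code{location},
#'   \code{n_observed}, \code{n_random}, \code{observed_pct},
#'   \code{random_pct}, \code{ter}, \code{above_threshold}.
#' @export
computeTER <- function(assignedPeaks, assignedRandom, classes = NULL,
                       terThreshold = 2) {
  obs <- assignedPeaks[assignedPeaks$assigned, , drop = FALSE]
  rnd <- assignedRandom[assignedRandom$assigned, , drop = FALSE]
  if (is.null(classes))
    classes <- sort(unique(c(obs$gene_class, rnd$gene_class)))
  grid <- expand.grid(gene_class = classes,
                      location = c("proximal", "distal"),
                      stringsAsFactors = FALSE)
  cell <- function(df, cls, loc) {
    sum(df$gene_class == cls & (df$proximal == (loc == "proximal")))
  }
  nObs <- mapply(cell, cls = grid$gene_class, loc = grid$location,
                 MoreArgs = list(df = obs))
  nRnd <- mapply(cell, cls = grid$gene_class, loc = grid$location,
                 MoreArgs = list(df = rnd))
  obsPct <- if (nrow(obs)) 100 * nObs / nrow(obs) else rep(0, nrow(grid))
  rndPct <- if (nrow(rnd)) 100 * nRnd / nrow(rnd) else rep(0, nrow(grid))
  ter <- ifelse(rndPct > 0, obsPct / rndPct,
                ifelse(obsPct > 0, Inf, NA_real_))
  data.frame(grid, n_observed = nObs, n_random = nRnd,
             observed_pct = obsPct, random_pct = rndPct, ter = ter,
             above_threshold = !is.na(ter) & ter > terThreshold)
}

#' TSS-anchored binding profile
#'
#' For every gene of a class, counts peaks (by their center) in 401 windows
#' of \code{windowBp} bp spanning TSS +/- \code{flankKb} kb, window 0
#' centered at the TSS, oriented by gene strand. Windows whose genomic span
#' extends beyond the gene's tiled segment are missing (NA), not zero, and
#' are ignored when averaging across genes.
#'
#' @param peaks GRanges of peaks.
#' @param genes GRanges of width-1 TSS positions (\code{gene_id} required).
#' @param segments GRanges of the tiled segments.
#' @param flankKb half-range in kb (default 200).
#' @param windowBp window width in bp (default 1000).
#' @return list with \code{profile} (data.frame: \code{window},
#'   \code{mean_frequency}, \code{n_genes}) and \code{counts} (genes x
#'   windows matrix with NA for missing windows).
#' @export
bindingProfile <- function(peaks, genes, segments, flankKb = 200L,
                           windowBp = 1000L) {
  if (!length(genes)) stop("genes must be non-empty")
  nw <- 2L * flankKb * 1000L %/% windowBp + 1L
  half <- windowBp %/% 2L
  wins <- seq_len(nw) - 1L - (nw - 1L) %/% 2L  # -200 .. 200
  center <- floor((start(peaks) + end(peaks)) / 2)
  pchrom <- as.character(seqnames(peaks))
  counts <- matrix(NA_real_, nrow = length(genes), ncol = nw,
                   dimnames = list(genes$gene_id, wins))
  segChrom <- as.character(seqnames(segments))
  for (g in seq_along(genes)) {
    chrom <- as.character(seqnames(genes)[g])
    tss <- start(genes)[g]
    sgn <- if (as.character(strand(genes)[g]) == "-") -1L else 1L
    seg <- segments[segChrom == chrom &
                      start(segments) <= tss & end(segments) >= tss]
    if (!length(seg)) next
    ## genomic span of oriented window k: tss + sgn*k*windowBp +/- half
    wcen <- tss + sgn * wins * windowBp
    inSeg <- (wcen - half) >= start(seg)[1L] & (wcen + half - 1L) <= end(seg)[1L]
    counts[g, inSeg] <- 0
    pc <- center[pchrom == chrom]
    if (length(pc)) {
      rel <- sgn * (pc - tss)
      k <- floor((rel + half) / windowBp)
      k <- k[k >= min(wins) & k <= max(wins)]
      if (length(k)) {
        tb <- table(k)
        idx <- match(as.integer(names(tb)), wins)
        hitIdx <- idx[inSeg[idx]]
        counts[g, hitIdx] <- as.integer(tb)[inSeg[idx]]
      }
    }
  }
  nGenes <- colSums(!is.na(counts))
  meanFreq <- ifelse(nGenes > 0, colMeans(counts, na.rm = TRUE), NA_real_)
  list(profile = data.frame(window = wins, mean_frequency = meanFreq,
                            n_genes = nGenes),
       counts = counts)
}

#' Per-segment binding statistics
#'
#' Per segment (and overall): STAT1/IRF1 peak counts, the IRF1:STAT1 ratio,
#' the fraction of each TF's peaks within \code{proximalBp} of a gene TSS
#' (excluding and including pseudogenes), the known-ISG fraction of genes,
#' and the density of early strong induced ISGs per Mb. Ratios are reported
#' to one decimal and are undefined (NA) when the segment has no STAT1
#' peaks.
#'
#' @param peaks GRanges of peaks with a \code{tf} metadata column.
#' @param genes GRanges of TSSs with \code{gene_id}, \code{class},
#'   \code{known_isg}, \code{pseudogene}.
#' @param segments GRanges of tiled segments.
#' @param proximalBp proximal cutoff (default 5000, inclusive).
#' @return data.frame with one row per segment plus an \code{"overall"} row.
#' @export
segmentStats <- function(peaks, genes, segments, proximalBp = 5000) {
  segNames <- as.character(seqnames(segments))
  pchrom <- as.character(seqnames(peaks))
  center <- floor((start(peaks) + end(peaks)) / 2)
  gchrom <- as.character(seqnames(genes))
  pseudo <- if ("pseudogene" %in% names(mcols(genes))) genes$pseudogene else
    rep(FALSE, length(genes))
  nearTss <- function(pidx, gidx) {
    if (!length(gidx)) return(rep(FALSE, length(pidx)))
    vapply(pidx, function(p)
      any(abs(center[p] - start(genes)[gidx]) <= proximalBp), logical(1))
  }
  row <- function(name, pidx, gidx, mb) {
    isS <- peaks$tf[pidx] == "STAT1"
    isI <- peaks$tf[pidx] == "IRF1"
    gReal <- gidx[!pseudo[gidx]]
    proxReal <- nearTss(pidx, gReal)
    proxAny <- proxReal | nearTss(pidx, gidx)
    nS <- sum(isS); nI <- sum(isI)
    propOr0 <- function(num, den) if (den > 0) num / den else NA_real_
    data.frame(
      segment = name, mb = mb, n_stat1 = nS, n_irf1 = nI,
      irf1_stat1_ratio = if (nS > 0) round(nI / nS, 1L) else NA_real_,
      stat1_proximal_frac = propOr0(sum(proxReal & isS), nS),
      irf1_proximal_frac = propOr0(sum(proxReal & isI), nI),
      stat1_proximal_frac_pseudo = propOr0(sum(proxAny & isS), nS),
      irf1_proximal_frac_pseudo = propOr0(sum(proxAny & isI), nI),
      n_genes = length(gReal),
      n_known_isg = sum(genes$known_isg[gReal]),
      isg_frac = propOr0(sum(genes$known_isg[gReal]), length(gReal)),
      n_es_indisg = sum(genes$class[gReal] == "es-indISG"),
      es_indisg_per_mb = round(sum(genes$class[gReal] == "es-indISG") / mb, 1L))
  }
  rows <- lapply(seq_along(segments), function(si) {
    s <- segNames[si]
    row(s, which(pchrom == s), which(gchrom == s),
        width(segments)[si] / 1e6)
  })
  rows[[length(rows) + 1L]] <- row("overall", seq_along(peaks),
                                   seq_along(genes), sum(width(segments)) / 1e6)
  do.call(rbind, rows)
}

#' Basal versus induced peak fractions
#'
#' Reports per TF the number of basal and induced peaks and basal counts as
#' a percentage of induced counts (one decimal).
#'
#' @param peaks GRanges with \code{tf} and \code{condition} metadata columns.
#' @return data.frame with columns \code{tf}, \code{n_basal},
#'   \code{n_induced}, \code{basal_pct_of_induced}.
#' @export
basalInducedSummary <- function(peaks) {
  tfs <- sort(unique(peaks$tf))
  do.call(rbind, lapply(tfs, function(tf) {
    nb <- sum(peaks$tf == tf & peaks$condition == "basal")
    ni <- sum(peaks$tf == tf & peaks$condition == "induced")
    data.frame(tf = tf, n_basal = nb, n_induced = ni,
               basal_pct_of_induced = if (ni > 0) round(100 * nb / ni, 1L)
                                      else NA_real_)
  }))
}
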