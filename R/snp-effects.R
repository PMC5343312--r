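## SNP allele-effect scoring: +/-50 bp context extraction, best overlapping
## motif likelihood per allele with NULL -> 0 semantics, 1.5-fold
## affinity-change classification, and the peaks -> motifs -> scores screen.

#' Extract reference and variant context around a SNP
#'
#' Returns the +/- \code{flank} bp sequence around the SNP for both alleles;
#' the two sequences differ only at the SNP base. Contexts are truncated at
#' segment edges (each side independently), and the SNP's position within
#' the context is reported so downstream scoring can anchor on it. If the
#' genome base does not match the declared reference a warning is issued and
#' the declared reference is used.
#'
#' @param snp list or one-row data.frame with \code{chrom}, \code{pos}
#'   (0-based), \code{ref}, \code{alt}.
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param flank context half-width in bp (default 50).
#' @return list with \code{ref}, \code{var} (character sequences),
#'   \code{offset} (1-based SNP position within the context) and
#'   \code{start0} (0-based genomic start of the context).
#' @export
extractContext <- function(snp, genome, flank = 50L) {
  chrom <- as.character(snp$chrom)
  pos <- as.integer(snp$pos)
  ref <- toupper(as.character(snp$ref)); alt <- toupper(as.character(snp$alt))
  if (!alt %in% BASES) stop(sprintf("alt allele '%s' is not in ACGT", alt))
  if (!ref %in% BASES) stop(sprintf("ref allele '%s' is not in ACGT", ref))
  if (ref == alt) stop("ref and alt must differ")
  if (!chrom %in% names(genome)) stop(sprintf("unknown segment '%s'", chrom))
  seqLen <- length(genome[[chrom]])
  if (pos < 0L || pos >= seqLen) stop("SNP position outside the segment")
  left <- max(1L, pos + 1L - flank)
  right <- min(seqLen, pos + 1L + flank)
  ctx <- as.character(Biostrings::subseq(genome[[chrom]], left, right))
  offset <- pos + 1L - left + 1L
  observed <- substr(ctx, offset, offset)
  if (observed != ref)
    warning(sprintf("genome base '%s' at %s:%d does not match declared ref '%s'; using declared ref",
                    observed, chrom, pos, ref))
  refSeq <- ctx; substr(refSeq, offset, offset) <- ref
  varSeq <- ctx; substr(varSeq, offset, offset) <- alt
  list(ref = refSeq, var = varSeq, offset = offset, start0 = left - 1L)
}

#' Score a SNP's effect on a motif
#'
#' Scans both allele contexts with the PWM and takes, per allele, the
#' maximum likelihood ratio among hits whose window covers the SNP position
#' (0 when no overlapping window clears \code{lrMin} — the NULL-allele
#' convention). The fold change is lr_var / lr_ref when lr_ref > 0 and
#' undefined (NA) otherwise. Verdicts: \code{gain} when the reference is
#' NULL and the variant scores, or fold change >= \code{cutoff};
#' \code{loss} mirrored; \code{null_both} when neither allele scores;
#' \code{neutral} otherwise.
#'
#' @param refSeq,varSeq allele context sequences (same coordinates, single
#'   differing base).
#' @param offset 1-based SNP position within the sequences.
#' @param pwm a \linkS4class{PwmModel}.
#' @param background a \linkS4class{MarkovBackground}.
#' @param lrMin motif hit threshold (default 500).
#' @param cutoff affinity fold-change cutoff (default 1.5, applied
#'   symmetrically: gain at >= 1.5, loss at <= 1/1.5).
#' @return data.frame row: \code{motif}, \code{lr_ref}, \code{lr_var},
#'   \code{fold_change}, \code{verdict}.
#' @export
scoreAllelePair <- function(refSeq, varSeq, offset, pwm, background,
                            lrMin = 500, cutoff = 1.5) {
  L <- motifLength(pwm)
  n <- nchar(refSeq)
  if (nchar(varSeq) != n) stop("allele sequences must have equal length")
  if (L > n)
    stop("motif is longer than the context; no window can overlap the SNP")
  bestLr <- function(seq) {
    hits <- scanMotifs(setNames(Biostrings::DNAStringSet(seq), "ctx"),
                       pwm, background, lrMin = lrMin)
    hits <- hits[start(hits) <= offset & end(hits) >= offset]
    if (length(hits)) max(hits$lr) else 0
  }
  lrRef <- bestLr(refSeq)
  lrVar <- bestLr(varSeq)
  fold <- if (lrRef > 0) lrVar / lrRef else NA_real_
  verdict <- if (lrRef == 0 && lrVar == 0) "null_both"
    else if (lrRef == 0) "gain"
    else if (lrVar == 0) "loss"
    else if (fold >= cutoff) "gain"
    else if (fold <= 1 / cutoff) "loss"
    else "neutral"
  data.frame(motif = motifName(pwm), lr_ref = lrRef, lr_var = lrVar,
             fold_change = fold, verdict = verdict)
}

#' Screen SNPs through the peak and motif filters
#'
#' Pipeline filter: keep SNPs inside called peaks, then SNPs covered by a
#' motif hit, then score each remaining SNP against every motif whose hit it
#' overlaps with [scoreAllelePair()]. Stage counts are reported alongside
#' the effects and are non-increasing along the screen.
#'
#' @param snps data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (0-based), \code{ref}, \code{alt}.
#' @param peaks \link[GenomicRanges]{GRanges} of called peaks.
#' @param motifHits GRanges from [scanMotifs()] in genomic coordinates, with
#'   \code{motif} metadata.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param pwms named list of \linkS4class{PwmModel}s (names matching the
#'   \code{motif} column of \code{motifHits}).
#' @param background a \linkS4class{MarkovBackground}.
#' @param flank,lrMin,cutoff passed to the scoring steps.
#' @return list with \code{effects} (data.frame: \code{snp_id},
#'   \code{motif}, \code{lr_ref}, \code{lr_var}, \code{fold_change},
#'   \code{verdict}) and \code{counts} (named: \code{total},
#'   \code{in_peaks}, \code{in_motifs}, \code{scored}).
#' @export
screenSnps <- function(snps, peaks, motifHits, genome, pwms, background,
                       flank = 50L, lrMin = 500, cutoff = 1.5) {
  total <- nrow(snps)
  emptyEffects <- data.frame(snp_id = character(), motif = character(),
                             lr_ref = numeric(), lr_var = numeric(),
                             fold_change = numeric(), verdict = character())
  if (!total)
    return(list(effects = emptyEffects,
                counts = c(total = 0L, in_peaks = 0L, in_motifs = 0L,
                           scored = 0L)))
  snpGr <- GRanges(snps$chrom, IRanges(snps$pos + 1L, width = 1L))
  inPeak <- overlapsAny(snpGr, peaks)
  stage1 <- snps[inPeak, , drop = FALSE]
  gr1 <- snpGr[inPeak]
  ov <- findOverlaps(gr1, motifHits)
  inMotif <- unique(S4Vectors::queryHits(ov))
  effects <- list()
  for (qi in inMotif) {
    motifs <- unique(motifHits$motif[S4Vectors::subjectHits(ov)[
      S4Vectors::queryHits(ov) == qi]])
    ctx <- extractContext(stage1[qi, ], genome, flank = flank)
    for (m in motifs) {
      pwm <- pwms[[m]]
      if (is.null(pwm)) next
      eff <- scoreAllelePair(ctx$ref, ctx$var, ctx$offset, pwm, background,
                             lrMin = lrMin, cutoff = cutoff)
      eff <- cbind(snp_id = stage1$id[qi], eff)
      effects[[length(effects) + 1L]] <- eff
    }
  }
  effects <- if (length(effects)) do.call(rbind, effects) else emptyEffects
  list(effects = effects,
       counts = c(total = total, in_peaks = nrow(stage1),
                  in_motifs = length(inMotif),
                  scored = length(unique(effects$snp_id))))
}
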