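## Synthetic-data generators: genome with planted motif instances and SNPs,
## tiling-array intensities with planted enrichment, and expression time
## courses that realise a declared response class. Everything is a pure
## function of (spec, seed) so tests can assert exact determinism.

#' Gene expression response class vocabulary
#'
#' The nine response classes assigned by [classifyGene()]: early/late x
#' strong/weak induced ISGs, resistant ISGs, late strong/weak repressed
#' genes (IRGs), potential ISGs and other genes.
#' @export
GENE_CLASSES <- c("es-indISG", "ls-indISG", "ew-indISG", "lw-indISG",
                  "resISG", "ls-IRG", "lw-IRG", "potISG", "other")

emptyPeaks <- function() data.frame(segment = character(), start = integer(),
                                    end = integer(), fold = numeric(),
                                    tf = character(), condition = character())
emptyMotifs <- function() data.frame(segment = character(), pos = integer(),
                                     strand = character(), name = character(),
                                     seq = character())
emptySnps <- function() data.frame(id = character(), segment = character(),
                                   pos = integer(), ref = character(),
                                   alt = character())
emptyGenes <- function() data.frame(gene_id = character(), segment = character(),
                                    tss = integer(), strand = character(),
                                    class = character(), known_isg = logical(),
                                    pot_isg = logical(), pseudogene = logical())

#' Construct a synthetic study specification
#'
#' @param seed integer root seed.
#' @param segments data.frame with columns \code{name}, \code{length}.
#' @param probeSpacing,probeLen,nReplicates array geometry: probe spacing
#'   (default 80 bp), probe length (default 50 bp, i.e. 50-mers) and number
#'   of biological replicates (default 3).
#' @param plantedPeaks,plantedMotifs,plantedSnps,geneTemplates ground-truth
#'   tables; see \linkS4class{SyntheticSpec} for their columns.
#' @param noiseSdLog2 per-probe per-replicate multiplicative noise, sd on the
#'   log2 scale (default 0.25).
#' @param baselineLog2Mean,baselineLog2Sd per-probe baseline intensity
#'   distribution on the log2 scale (defaults 10 and 1).
#' @return a validated \linkS4class{SyntheticSpec}.
#' @examples
#' sp <- syntheticSpec(seed = 1L,
#'                     segments = data.frame(name = "segA", length = 10000L))
#' sp
#' @export
syntheticSpec <- function(seed, segments,
                          probeSpacing = 80L, probeLen = 50L, nReplicates = 3L,
                          plantedPeaks = emptyPeaks(),
                          plantedMotifs = emptyMotifs(),
                          plantedSnps = emptySnps(),
                          geneTemplates = emptyGenes(),
                          noiseSdLog2 = 0.25,
                          baselineLog2Mean = 10, baselineLog2Sd = 1) {
  new("SyntheticSpec", seed = as.integer(seed), segments = segments,
      probeSpacing = as.integer(probeSpacing), probeLen = as.integer(probeLen),
      nReplicates = as.integer(nReplicates),
      plantedPeaks = plantedPeaks, plantedMotifs = plantedMotifs,
      plantedSnps = plantedSnps, geneTemplates = geneTemplates,
      noiseSdLog2 = noiseSdLog2, baselineLog2Mean = baselineLog2Mean,
      baselineLog2Sd = baselineLog2Sd)
}

#' Generate a synthetic genome and gene annotation
#'
#' Draws an i.i.d. uniform A/C/G/T background for every segment, splices the
#' declared motif instances in at their positions (reverse-complemented on
#' the minus strand), then sets each planted SNP position to its reference
#' base. Overlapping planted motifs are an error. Deterministic for a fixed
#' spec.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a list with elements \code{genome} (a
#'   \link[Biostrings]{DNAStringSet}, one entry per segment) and \code{genes}
#'   (a \link[GenomicRanges]{GRanges} of width-1 TSS positions with metadata
#'   columns \code{gene_id}, \code{class}, \code{known_isg}, \code{pot_isg},
#'   \code{pseudogene}).
#' @export
generateGenome <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  seg <- spec@segments
  genome <- withSeed(deriveSeed(spec@seed, "genome"), {
    seqs <- vapply(seg$length, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(setNames(seqs, seg$name))
  })
  mo <- spec@plantedMotifs
  if (nrow(mo)) {
    ir <- split(IRanges(start = mo$pos + 1L, width = nchar(mo$seq)), mo$segment)
    for (s in names(ir)) {
      ov <- findOverlaps(ir[[s]], ir[[s]])
      ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
      if (length(ov)) {
        i <- which(mo$segment == s)
        stop(sprintf("overlapping planted motifs in segment %s: rows %d and %d",
                     s, i[S4Vectors::queryHits(ov)[1L]],
                     i[S4Vectors::subjectHits(ov)[1L]]))
      }
    }
    for (i in seq_len(nrow(mo))) {
      inst <- Biostrings::DNAString(mo$seq[i])
      if (mo$strand[i] == "-") inst <- Biostrings::reverseComplement(inst)
      genome[[mo$segment[i]]] <- Biostrings::replaceAt(
        genome[[mo$segment[i]]],
        IRanges(mo$pos[i] + 1L, width = length(inst)), inst)
    }
  }
  sn <- spec@plantedSnps
  for (i in seq_len(nrow(sn)))
    genome[[sn$segment[i]]] <- Biostrings::replaceAt(
      genome[[sn$segment[i]]], IRanges(sn$pos[i] + 1L, width = 1L),
      Biostrings::DNAString(sn$ref[i]))
  gt <- spec@geneTemplates
  genes <- GRanges(seqnames = if (nrow(gt)) gt$segment else character(),
                   ranges = IRanges(start = gt$tss + 1L, width = 1L),
                   strand = if (nrow(gt)) gt$strand else character(),
                   gene_id = gt$gene_id, class = gt$class,
                   known_isg = gt$known_isg, pot_isg = gt$pot_isg,
                   pseudogene = gt$pseudogene,
                   seqlengths = setNames(seg$length, seg$name))
  list(genome = genome, genes = sort(genes, ignore.strand = TRUE))
}

#' Construct a TilingExperiment
#'
#' @param probes \link[GenomicRanges]{GRanges} of probe positions with a
#'   \code{probe_id} metadata column.
#' @param intensity numeric probe x sample matrix of strictly positive
#'   intensities.
#' @param channel character vector, \code{"chip"} or \code{"input"} per column.
#' @param replicate integer replicate index per column.
#' @param tf,condition experiment labels.
#' @param normalized logical, whether intensities are quantile normalized.
#' @return a \linkS4class{TilingExperiment}.
#' @export
tilingExperiment <- function(probes, intensity, channel, replicate,
                             tf = NA_character_, condition = NA_character_,
                             normalized = FALSE) {
  rownames(intensity) <- probes$probe_id
  colnames(intensity) <- sprintf("%s_rep%d", channel, replicate)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), rowRanges = probes,
    colData = S4Vectors::DataFrame(channel = channel, replicate = replicate))
  S4Vectors::metadata(se) <- list(tf = tf, condition = condition,
                                  normalized = normalized)
  new("TilingExperiment", se)
}

probeLayout <- function(spec) {
  seg <- spec@segments
  short <- seg$name[seg$length < spec@probeLen]
  if (length(short))
    stop(sprintf("segment(s) too short to carry a probe: %s",
                 paste(short, collapse = ", ")))
  starts <- lapply(seg$length, function(len)
    seq.int(0L, len - spec@probeLen, by = spec@probeSpacing))
  gr <- GRanges(seqnames = rep(seg$name, lengths(starts)),
                ranges = IRanges(start = unlist(starts) + 1L,
                                 width = spec@probeLen),
                seqlengths = setNames(seg$length, seg$name))
  gr$probe_id <- sprintf("%s_p%06d", as.character(seqnames(gr)),
                         unlist(lapply(lengths(starts), seq_len)))
  gr
}

#' Generate a replicated tiling-array ChIP/input experiment
#'
#' Tiles every segment with probes at the spec's spacing and draws
#' intensities: each probe has a shared lognormal baseline; every array value
#' multiplies that baseline by independent lognormal noise (sd
#' \code{noiseSdLog2} in log2 units), and ChIP values for probes overlapping
#' a planted peak of the matching TF and condition are additionally
#' multiplied by the peak's enrichment fold. Quadruplicate spots are emitted
#' pre-averaged, i.e. one value per probe per replicate.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param tfs,conditions which TF / condition combinations to simulate.
#' @return a list with \code{experiments} (named list of raw
#'   \linkS4class{TilingExperiment}s, names \code{"{tf}_{condition}"}),
#'   \code{probes} (the shared probe map) and \code{truth} (GRanges of the
#'   planted peaks with \code{tf}, \code{condition}, \code{fold}).
#' @export
generateTilingExperiment <- function(spec, tfs = c("STAT1", "IRF1"),
                                     conditions = c("basal", "induced")) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  probes <- probeLayout(spec)
  pk <- spec@plantedPeaks
  truth <- GRanges(seqnames = if (nrow(pk)) pk$segment else character(),
                   ranges = IRanges(start = pk$start + 1L,
                                    end = pmax(pk$end, pk$start + 1L)),
                   tf = pk$tf, condition = pk$condition, fold = pk$fold,
                   seqlengths = seqlengths(probes))
  nrep <- spec@nReplicates
  experiments <- list()
  for (tf in tfs) for (cond in conditions) {
    key <- paste(tf, cond, sep = "_")
    fold <- rep(1, length(probes))
    sel <- truth[(truth$tf == tf | truth$tf == "both") & truth$condition == cond]
    if (length(sel)) {
      ov <- findOverlaps(probes, sel)
      if (length(ov)) {
        f <- tapply(sel$fold[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), max)
        fold[as.integer(names(f))] <- as.numeric(f)
      }
    }
    experiments[[key]] <- withSeed(deriveSeed(spec@seed, key), {
      n <- length(probes)
      base <- rnorm(n, spec@baselineLog2Mean, spec@baselineLog2Sd)
      mat <- matrix(0, n, 2L * nrep)
      for (r in seq_len(nrep)) {
        mat[, r] <- 2^(base + log2(fold) + rnorm(n, 0, spec@noiseSdLog2))
        mat[, nrep + r] <- 2^(base + rnorm(n, 0, spec@noiseSdLog2))
      }
      tilingExperiment(probes, mat,
                       channel = rep(c("chip", "input"), each = nrep),
                       replicate = rep(seq_len(nrep), 2L),
                       tf = tf, condition = cond)
    })
  }
  list(experiments = experiments, probes = probes, truth = truth)
}

## Draw one (fold, diff) pair per timepoint realising a target class.
## "none" draws are kept well inside the no-call region (|diff| < 13).
drawCourse <- function(class) {
  none <- function() c(runif(1, 0.85, 1.18), runif(1, -8, 8))
  strongInd <- function() c(runif(1, 2.2, 6), runif(1, 15, 40))
  weakInd <- function() c(runif(1, 1.25, 1.9), runif(1, 13.5, 30))
  strongRep <- function() c(runif(1, 0.2, 0.45), runif(1, -35, -15))
  weakRep <- function() c(runif(1, 0.55, 0.9), runif(1, -30, -13.5))
  rows <- switch(class,
    "es-indISG" = list(strongInd(), strongInd(), weakInd()),
    "ew-indISG" = list(weakInd(), weakInd(), none()),
    "ls-indISG" = list(none(), strongInd(), strongInd()),
    "lw-indISG" = list(none(), weakInd(), weakInd()),
    "ls-IRG"    = list(none(), strongRep(), strongRep()),
    "lw-IRG"    = list(none(), weakRep(), weakRep()),
    "resISG"    = ,
    "potISG"    = ,
    "other"     = list(none(), none(), none()),
    stop(sprintf("unknown expression class '%s'", class)))
  m <- do.call(rbind, rows)
  data.frame(timepoint_h = c(6L, 24L, 48L), fold_change = m[, 1L],
             diff_score = m[, 2L])
}

#' Generate per-gene expression time courses
#'
#' Emits a fold change and differential score at 6, 24 and 48 h for every
#' gene template, drawn so that the course satisfies the class-definition
#' rules for the declared label: [classifyGene()] recovers the template class
#' exactly (round-trip property). Known-ISG and potential-ISG flags are
#' derived from the class.
#'
#' @param spec a \linkS4class{SyntheticSpec} with non-empty
#'   \code{geneTemplates}.
#' @return data.frame with columns \code{gene_id}, \code{timepoint_h},
#'   \code{fold_change}, \code{diff_score}, \code{known_isg}, \code{pot_isg}.
#' @export
generateExpressionTable <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  gt <- spec@geneTemplates
  if (!nrow(gt)) stop("spec has no gene templates")
  bad <- setdiff(unique(gt$class), GENE_CLASSES)
  if (length(bad))
    stop(sprintf("unknown expression class(es): %s", paste(bad, collapse = ", ")))
  withSeed(deriveSeed(spec@seed, "expression"), {
    out <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
      df <- drawCourse(gt$class[i])
      df$gene_id <- gt$gene_id[i]
      df
    }))
    known <- gt$class %in% c("es-indISG", "ls-indISG", "ew-indISG",
                             "lw-indISG", "resISG")
    pot <- gt$class == "potISG"
    out$known_isg <- rep(known, each = 3L)
    out$pot_isg <- rep(pot, each = 3L)
    out[, c("gene_id", "timepoint_h", "fold_change", "diff_score",
            "known_isg", "pot_isg")]
  })
}
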