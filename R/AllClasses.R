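#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels "seqlevels<-"
#' @import SummarizedExperiment
NULL

setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' Synthetic study specification
#'
#' Describes a synthetic tiling-array study: genome segments, probe layout,
#' replicate structure, planted enrichment regions, planted motif instances
#' and SNPs, the multiplicative noise level, and gene templates with target
#' expression classes. All generators are pure functions of the spec
#' (including its seed), so a spec fully determines every simulated input.
#'
#' Coordinates in the spec are 0-based half-open, matching BED conventions;
#' objects returned by the generators use the usual 1-based Bioconductor
#' conventions.
#'
#' @slot seed integer root seed for all generators.
#' @slot segments data.frame with columns \code{name}, \code{length} (bp).
#' @slot probeSpacing integer, center-to-center probe spacing in bp.
#' @slot probeLen integer, probe length in bp (50-mers by default).
#' @slot nReplicates integer, biological replicates per channel.
#' @slot plantedPeaks data.frame with columns \code{segment}, \code{start},
#'   \code{end} (0-based half-open), \code{fold} (>= 1), \code{tf}
#'   (\code{"STAT1"}, \code{"IRF1"} or \code{"both"}) and \code{condition}
#'   (\code{"basal"} or \code{"induced"}).
#' @slot plantedMotifs data.frame with columns \code{segment}, \code{pos}
#'   (0-based), \code{strand} (\code{"+"}/\code{"-"}), \code{name},
#'   \code{seq} (the instance spliced into the genome).
#' @slot plantedSnps data.frame with columns \code{id}, \code{segment},
#'   \code{pos} (0-based), \code{ref}, \code{alt}.
#' @slot noiseSdLog2 numeric, per-probe per-replicate noise sd in log2 units.
#' @slot baselineLog2Mean,baselineLog2Sd numeric, distribution of the shared
#'   per-probe baseline intensity on the log2 scale.
#' @slot geneTemplates data.frame with columns \code{gene_id}, \code{segment},
#'   \code{tss} (0-based), \code{strand}, \code{class} (target expression
#'   class), \code{known_isg}, \code{pot_isg}, \code{pseudogene} (logical).
#'
#' @seealso [syntheticSpec()], [generateGenome()],
#'   [generateTilingExperiment()], [generateExpressionTable()]
#' @export
setClass("SyntheticSpec",
  representation(
    seed = "integer",
    segments = "data.frame",
    probeSpacing = "integer",
    probeLen = "integer",
    nReplicates = "integer",
    plantedPeaks = "data.frame",
    plantedMotifs = "data.frame",
    plantedSnps = "data.frame",
    noiseSdLog2 = "numeric",
    baselineLog2Mean = "numeric",
    baselineLog2Sd = "numeric",
    geneTemplates = "data.frame"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  seg <- object@segments
  if (!all(c("name", "length") %in% names(seg)))
    msg <- c(msg, "segments needs columns 'name' and 'length'")
  else {
    if (anyDuplicated(seg$name)) msg <- c(msg, "segment names must be unique")
    if (any(seg$length <= 0)) msg <- c(msg, "segment lengths must be > 0")
  }
  if (object@probeSpacing < 1L) msg <- c(msg, "probeSpacing must be >= 1")
  if (object@probeLen < 1L) msg <- c(msg, "probeLen must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@noiseSdLog2 < 0) msg <- c(msg, "noiseSdLog2 must be >= 0")
  segLen <- setNames(seg$length, seg$name)
  inSeg <- function(segment, pos, what) {
    bad <- !(segment %in% seg$name) | pos < 0 | pos >= segLen[segment]
    if (any(bad)) sprintf("%s outside declared segments: %s", what,
                          paste(which(bad), collapse = ", "))
    else character()
  }
  pk <- object@plantedPeaks
  if (nrow(pk)) {
    if (any(pk$end <= pk$start)) msg <- c(msg, "plantedPeaks: end must be > start")
    if (any(pk$fold < 1)) msg <- c(msg, "plantedPeaks: fold must be >= 1")
    if (!all(pk$tf %in% c("STAT1", "IRF1", "both")))
      msg <- c(msg, "plantedPeaks: tf must be STAT1, IRF1 or both")
    if (!all(pk$condition %in% c("basal", "induced")))
      msg <- c(msg, "plantedPeaks: condition must be basal or induced")
    msg <- c(msg, inSeg(pk$segment, pk$start, "plantedPeaks"))
    msg <- c(msg, inSeg(pk$segment, pk$end - 1L, "plantedPeaks"))
  }
  mo <- object@plantedMotifs
  if (nrow(mo)) {
    msg <- c(msg, inSeg(mo$segment, mo$pos, "plantedMotifs"))
    msg <- c(msg, inSeg(mo$segment, mo$pos + nchar(mo$seq) - 1L, "plantedMotifs"))
    if (!all(mo$strand %in% c("+", "-")))
      msg <- c(msg, "plantedMotifs: strand must be '+' or '-'")
  }
  sn <- object@plantedSnps
  if (nrow(sn)) {
    msg <- c(msg, inSeg(sn$segment, sn$pos, "plantedSnps"))
    if (!all(sn$ref %in% c("A", "C", "G", "T")) || !all(sn$alt %in% c("A", "C", "G", "T")))
      msg <- c(msg, "plantedSnps: ref and alt must be single bases in ACGT")
    if (any(sn$ref == sn$alt)) msg <- c(msg, "plantedSnps: ref must differ from alt")
  }
  gt <- object@geneTemplates
  if (nrow(gt)) {
    msg <- c(msg, inSeg(gt$segment, gt$tss, "geneTemplates"))
    if (anyDuplicated(gt$gene_id)) msg <- c(msg, "gene_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Tiling-array intensity experiment
#'
#' A \linkS4class{RangedSummarizedExperiment} holding probe-level intensities
#' for one transcription factor in one condition. Rows are tiling probes
#' (\code{rowRanges}); columns are arrays, with \code{colData} columns
#' \code{channel} (\code{"chip"} or \code{"input"}) and \code{replicate}.
#' The single assay \code{"intensity"} must be finite and strictly positive.
#' Metadata fields \code{tf}, \code{condition} and \code{normalized} track
#' provenance through the pipeline.
#'
#' @seealso [tilingExperiment()], [quantileNormalize()], [windowTest()]
#' @export
setClass("TilingExperiment", contains = "RangedSummarizedExperiment")

setValidity("TilingExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  m <- SummarizedExperiment::assay(object, "intensity")
  if (ncol(m) < 1L) msg <- c(msg, "at least one sample column is required")
  bad <- !is.finite(m) | m <= 0
  if (any(bad)) {
    ids <- rownames(m)[which(rowSums(bad) > 0)]
    msg <- c(msg, sprintf("non-finite or non-positive intensities at probes: %s",
                          paste(head(ids, 5L), collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("channel", "replicate") %in% names(cd)))
    msg <- c(msg, "colData needs 'channel' and 'replicate'")
  else if (!all(cd$channel %in% c("chip", "input")))
    msg <- c(msg, "channel must be 'chip' or 'input'")
  rr <- SummarizedExperiment::rowRanges(object)
  if (is.unsorted(order(as.integer(seqnames(rr)), start(rr))))
    msg <- c(msg, "probes must be sorted by (chrom, start)")
  if (length(msg)) msg else TRUE
})

#' Position weight matrix with pseudo-counts
#'
#' A position frequency matrix (base counts per motif column) together with
#' its pseudo-count-regularised probability form. Rows are A, C, G, T;
#' columns are motif positions. Each probability column sums to 1.
#'
#' @slot name motif name (e.g. a JASPAR identifier).
#' @slot counts 4 x L non-negative count matrix (rows A, C, G, T).
#' @slot pseudocount positive pseudo-count added to every cell.
#' @slot probs 4 x L column-stochastic probability matrix.
#'
#' @seealso [buildPwm()], [readJasparPfm()], [scanMotifs()]
#' @export
setClass("PwmModel",
  representation(name = "character", counts = "matrix",
                 pseudocount = "numeric", probs = "matrix"))

setValidity("PwmModel", function(object) {
  msg <- character()
  if (nrow(object@counts) != 4L) msg <- c(msg, "counts must have 4 rows (A,C,G,T)")
  if (ncol(object@counts) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be > 0")
  cs <- colSums(object@probs)
  if (any(abs(cs - 1) > 1e-9)) msg <- c(msg, "probability columns must sum to 1")
  if (length(msg)) msg else TRUE
})

#' k-th order Markov background model
#'
#' Conditional probabilities P(base | preceding k-mer) estimated from
#' training sequence with add-one smoothing, so every context is defined.
#' The order-0 marginal composition is kept alongside and used for window
#' positions with fewer than k preceding bases.
#'
#' @slot order the Markov order k (>= 0).
#' @slot cond 4^k x 4 matrix of conditional probabilities; rows are contexts
#'   in lexicographic A<C<G<T order, columns are the next base.
#' @slot stationary length-4 marginal base composition (smoothed).
#' @slot trainingBp total bases used for training.
#'
#' @seealso [fitBackground()], [scanMotifs()]
#' @export
setClass("MarkovBackground",
  representation(order = "integer", cond = "matrix",
                 stationary = "numeric", trainingBp = "integer"))

setValidity("MarkovBackground", function(object) {
  msg <- character()
  k <- object@order
  if (k < 0L) msg <- c(msg, "order must be >= 0")
  if (nrow(object@cond) != 4L^k) msg <- c(msg, "cond must have 4^order rows")
  if (ncol(object@cond) != 4L) msg <- c(msg, "cond must have 4 columns")
  if (any(abs(rowSums(object@cond) - 1) > 1e-9))
    msg <- c(msg, "each conditional distribution must sum to 1")
  if (abs(sum(object@stationary) - 1) > 1e-9)
    msg <- c(msg, "stationary composition must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Holds every threshold and path used by [runPipeline()], with the defaults
#' used throughout the analysis: window 500 bp, p < 1e-4, fold >= 1.5,
#' 500 bp merge, 5 kb proximal cutoff, LR > 500 with a 3rd-order background,
#' 1.5-fold SNP affinity cutoff and TER threshold 2. Round-trips through
#' YAML via [readPipelineConfig()] / [writePipelineConfig()].
#'
#' @slot params named list of parameters; see [pipelineConfig()].
#' @export
setClass("PipelineConfig", representation(params = "list"))

setValidity("PipelineConfig", function(object) {
  p <- object@params
  need <- c("seed", "p_max", "fold_min", "window_bp", "merge_bp", "proximal_bp",
            "lr_min", "bg_order", "snp_cutoff", "ter_threshold", "dual_link_bp",
            "include_pseudogenes", "n_random")
  miss <- setdiff(need, names(p))
  if (length(miss)) return(paste("missing parameters:", paste(miss, collapse = ", ")))
  pos <- c("p_max", "fold_min", "window_bp", "merge_bp", "proximal_bp", "lr_min",
           "snp_cutoff", "ter_threshold")
  bad <- pos[vapply(p[pos], function(v) !is.numeric(v) || v <= 0, logical(1))]
  if (length(bad)) return(paste("parameters must be positive:", paste(bad, collapse = ", ")))
  if (!isCount(p$bg_order, min = 0L)) return("bg_order must be a non-negative integer")
  TRUE
})
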