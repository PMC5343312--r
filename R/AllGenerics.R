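#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x, ...) standardGeneric("quantileNormalize"))

#' Accessors for TilingExperiment
#'
#' \code{isNormalized} reports whether intensities have been quantile
#' normalized; \code{chipMatrix} and \code{inputMatrix} return the intensity
#' columns of the ChIP and input channels; \code{tfName} and
#' \code{conditionName} return the experiment labels.
#'
#' @param x a \linkS4class{TilingExperiment}.
#' @return \code{isNormalized}: logical scalar; \code{chipMatrix},
#'   \code{inputMatrix}: numeric matrices (probes x replicates);
#'   \code{tfName}, \code{conditionName}: character scalars.
#' @name TilingExperiment-accessors
#' @aliases isNormalized chipMatrix inputMatrix tfName conditionName
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname TilingExperiment-accessors
#' @export
setGeneric("chipMatrix", function(x) standardGeneric("chipMatrix"))

#' @rdname TilingExperiment-accessors
#' @export
setGeneric("inputMatrix", function(x) standardGeneric("inputMatrix"))

#' @rdname TilingExperiment-accessors
#' @export
setGeneric("tfName", function(x) standardGeneric("tfName"))

#' @rdname TilingExperiment-accessors
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))

setMethod("isNormalized", "TilingExperiment", function(x)
  isTRUE(S4Vectors::metadata(x)$normalized))

setMethod("chipMatrix", "TilingExperiment", function(x)
  SummarizedExperiment::assay(x, "intensity")[, x$channel == "chip", drop = FALSE])

setMethod("inputMatrix", "TilingExperiment", function(x)
  SummarizedExperiment::assay(x, "intensity")[, x$channel == "input", drop = FALSE])

setMethod("tfName", "TilingExperiment", function(x)
  S4Vectors::metadata(x)$tf %||% NA_character_)

setMethod("conditionName", "TilingExperiment", function(x)
  S4Vectors::metadata(x)$condition %||% NA_character_)

setMethod("show", "TilingExperiment", function(object) {
  cat(sprintf("TilingExperiment: %s / %s (%s)\n",
              tfName(object), conditionName(object),
              if (isNormalized(object)) "normalized" else "raw"))
  cat(sprintf("  %d probes on %d sequence(s); %d chip + %d input arrays\n",
              nrow(object), length(unique(as.character(seqnames(object)))),
              sum(object$channel == "chip"), sum(object$channel == "input")))
  invisible(NULL)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec\n")
  cat(sprintf("  seed: %d; %d segment(s) totalling %.2f Mb\n",
              object@seed, nrow(object@segments), sum(object@segments$length) / 1e6))
  cat(sprintf("  probes: %d-mers every %d bp; %d replicates; noise sd %.2f (log2)\n",
              object@probeLen, object@probeSpacing, object@nReplicates,
              object@noiseSdLog2))
  cat(sprintf("  planted: %d peak(s), %d motif(s), %d SNP(s); %d gene template(s)\n",
              nrow(object@plantedPeaks), nrow(object@plantedMotifs),
              nrow(object@plantedSnps), nrow(object@geneTemplates)))
  invisible(NULL)
})

setMethod("show", "PwmModel", function(object) {
  cat(sprintf("PwmModel '%s': length %d, pseudocount %g\n",
              object@name, ncol(object@probs), object@pseudocount))
  consensus <- paste(rownames(object@probs)[apply(object@probs, 2L, which.max)],
                     collapse = "")
  cat(sprintf("  consensus: %s\n", consensus))
  invisible(NULL)
})

setMethod("show", "MarkovBackground", function(object) {
  cat(sprintf("MarkovBackground: order %d, trained on %d bp\n",
              object@order, object@trainingBp))
  cat(sprintf("  composition: A %.3f C %.3f G %.3f T %.3f\n",
              object@stationary[1L], object@stationary[2L],
              object@stationary[3L], object@stationary[4L]))
  invisible(NULL)
})

setMethod("show", "PipelineConfig", function(object) {
  p <- object@params
  cat("PipelineConfig\n")
  cat(sprintf("  seed %s | window %g bp, merge %g bp, p < %g, fold >= %g\n",
              p$seed, p$window_bp, p$merge_bp, p$p_max, p$fold_min))
  cat(sprintf("  proximal <= %g bp | LR > %g (order-%d bg) | SNP cutoff %g | TER %g\n",
              p$proximal_bp, p$lr_min, p$bg_order, p$snp_cutoff, p$ter_threshold))
  invisible(NULL)
})

#' Motif name accessor
#' @param x a \linkS4class{PwmModel}.
#' @return character scalar.
#' @export
motifName <- function(x) {
  stopifnot(is(x, "PwmModel"))
  x@name
}

#' Probability matrix accessor
#' @param x a \linkS4class{PwmModel}.
#' @return 4 x L column-stochastic matrix (rows A, C, G, T).
#' @export
pwmProbs <- function(x) {
  stopifnot(is(x, "PwmModel"))
  x@probs
}

#' Motif length accessor
#' @param x a \linkS4class{PwmModel}.
#' @return integer motif length.
#' @export
motifLength <- function(x) {
  stopifnot(is(x, "PwmModel"))
  ncol(x@probs)
}

#' Background order accessor
#' @param x a \linkS4class{MarkovBackground}.
#' @return integer Markov order.
#' @export
backgroundOrder <- function(x) {
  stopifnot(is(x, "MarkovBackground"))
  x@order
}
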