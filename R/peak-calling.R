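## Peak calling: quantile normalization, one-sided Wilcoxon rank-sum tests in
## a 500 bp probe-centred sliding window, and fold/p filtering with 500 bp
## merging of passing windows.

#' Quantile normalization of probe intensities
#'
#' Forces every array (column) onto the identical sorted value distribution
#' (the per-rank column means). Ties within a column receive the mean of the
#' tied ranks' reference values. Row order is preserved. Computation is
#' delegated to \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param x a positive numeric matrix (probes x arrays) or a
#'   \linkS4class{TilingExperiment}; at least two columns.
#' @param ... unused.
#' @return an object of the same class as \code{x}, normalized; for a
#'   \code{TilingExperiment} the \code{normalized} flag is set.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
#' quantileNormalize(m)  # both columns become (1.5, 3.0, 4.5)
#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 columns")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    id <- if (!is.null(rownames(x))) rownames(x)[bad[1L, 1L]] else
      sprintf("row %d", bad[1L, 1L])
    stop(sprintf("non-finite intensity at probe %s", id))
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "TilingExperiment", function(x, ...) {
  m <- SummarizedExperiment::assay(x, "intensity")
  SummarizedExperiment::assay(x, "intensity") <- quantileNormalize(m)
  S4Vectors::metadata(x)$normalized <- TRUE
  validObject(x)
  x
})

#' One-sided Wilcoxon rank-sum p-value
#'
#' Tests whether \code{x} is stochastically greater than \code{y}. For
#' \code{length(x) + length(y) <= exactMax} the p-value is computed by exact
#' enumeration of all labelings of the pooled mid-ranks (valid under ties);
#' larger samples use the normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction.
#'
#' @param x,y numeric samples (enrichment alternative: x > y).
#' @param exactMax largest pooled size for exhaustive enumeration
#'   (default 12).
#' @return p-value in \code{[0, 1]}.
#' @examples
#' rankSumP(c(8, 9, 10, 11, 12, 13), c(1, 2, 3, 4, 5, 6))
#' @export
rankSumP <- function(x, y, exactMax = 12L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) return(1)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exactMax) {
    sums <- combn(r, n1, FUN = sum)
    return(sum(sums >= w - 1e-9) / length(sums))
  }
  mu <- n1 * (n + 1) / 2
  tie <- tabulate(match(r, unique(r)))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

## Same statistic on a log scale for score computation without underflow.
rankSumLogP <- function(x, y, exactMax = 12L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) return(0)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exactMax) {
    sums <- combn(r, n1, FUN = sum)
    return(log(sum(sums >= w - 1e-9) / length(sums)))
  }
  mu <- n1 * (n + 1) / 2
  tie <- tabulate(match(r, unique(r)))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE, log.p = TRUE)
}

#' Probe-centred sliding-window rank-sum test
#'
#' For every probe, pools all ChIP replicate values of the probes whose
#' centers fall within the probe's center +/- \code{windowBp}/2, pools the
#' input values likewise, and tests ChIP > input with [rankSumP()]. The
#' window fold is mean(ChIP)/mean(input) over the pooled values. Windows
#' covering fewer than two probes are emitted with p = 1.
#'
#' @param x a normalized \linkS4class{TilingExperiment} carrying both
#'   channels. Alternatively pass ChIP and input as two experiments via
#'   \code{input}.
#' @param input optional second \code{TilingExperiment} holding the input
#'   channel when \code{x} holds only ChIP arrays; probe maps must agree.
#' @param windowBp window width in bp (default 500).
#' @return data.frame with one row per probe: \code{probe_id}, \code{chrom},
#'   \code{center}, \code{window_start}, \code{window_end} (1-based
#'   inclusive), \code{n_probes}, \code{n_chip}, \code{n_input},
#'   \code{fold}, \code{p_value}, \code{log_p}.
#' @export
windowTest <- function(x, input = NULL, windowBp = 500L) {
  stopifnot(is(x, "TilingExperiment"))
  if (is.null(input)) {
    chip <- chipMatrix(x); inp <- inputMatrix(x)
    if (ncol(chip) == 0L || ncol(inp) == 0L)
      stop("experiment must carry both chip and input channels")
  } else {
    stopifnot(is(input, "TilingExperiment"))
    if (!identical(granges(rowRanges(x)), granges(rowRanges(input))))
      stop("probe maps of chip and input experiments differ")
    if (!isNormalized(input)) warning("input experiment is not normalized")
    chip <- SummarizedExperiment::assay(x, "intensity")
    inp <- SummarizedExperiment::assay(input, "intensity")
  }
  if (!isNormalized(x)) warning("experiment is not normalized")
  pr <- rowRanges(x)
  chrom <- as.character(seqnames(pr))
  center <- (start(pr) + end(pr)) / 2
  half <- windowBp / 2
  n <- length(pr)
  lo <- integer(n); hi <- integer(n)
  for (s in unique(chrom)) {
    i <- which(chrom == s)
    cen <- center[i]  # sorted within chrom by class validity
    lo[i] <- i[findInterval(cen - half, cen, left.open = TRUE) + 1L]
    hi[i] <- i[findInterval(cen + half, cen)]
  }
  pv <- numeric(n); lp <- numeric(n); fold <- numeric(n); np <- hi - lo + 1L
  for (i in seq_len(n)) {
    cv <- chip[lo[i]:hi[i], ]
    iv <- inp[lo[i]:hi[i], ]
    fold[i] <- mean(cv) / mean(iv)
    if (np[i] < 2L) { pv[i] <- 1; lp[i] <- 0 } else {
      lp[i] <- rankSumLogP(cv, iv)
      pv[i] <- exp(lp[i])
    }
  }
  data.frame(probe_id = pr$probe_id, chrom = chrom, center = center,
             window_start = pmax(1, ceiling(center - half)),
             window_end = floor(center + half),
             n_probes = np, n_chip = np * ncol(chip), n_input = np * ncol(inp),
             fold = fold, p_value = pv, log_p = lp)
}

#' Call peaks from window statistics
#'
#' Keeps windows with \code{p_value < pMax} and \code{fold >= foldMin} and
#' merges passing windows whose spans lie within \code{mergeBp} of each other
#' on the same chromosome. Peak bounds are the union of contributing window
#' spans; the peak score is the best \code{-log10 p} and the peak fold the
#' best window fold among contributors.
#'
#' @param stats data.frame from [windowTest()].
#' @param pMax raw p-value cutoff (default 1e-4; applied strictly, no
#'   multiple-testing correction — this mirrors the filtering the window
#'   statistics were designed for).
#' @param foldMin minimum window fold (default 1.5, inclusive).
#' @param mergeBp maximum gap between merged window spans (default 500).
#' @param tf,condition labels attached to the peaks.
#' @return \link[GenomicRanges]{GRanges} of peaks with metadata columns
#'   \code{tf}, \code{condition}, \code{score}, \code{fold},
#'   \code{n_windows}, sorted; empty when no window passes.
#' @export
callPeaks <- function(stats, pMax = 1e-4, foldMin = 1.5, mergeBp = 500L,
                      tf = NA_character_, condition = NA_character_) {
  keep <- stats$p_value < pMax & stats$fold >= foldMin
  empty <- GRanges(tf = character(), condition = character(),
                   score = numeric(), fold = numeric(), n_windows = integer())
  if (!any(keep)) return(empty)
  s <- stats[keep, , drop = FALSE]
  win <- GRanges(s$chrom, IRanges(s$window_start, s$window_end))
  peaks <- reduce(win, min.gapwidth = mergeBp + 1L)
  ov <- findOverlaps(win, peaks, maxgap = 0L)
  grp <- S4Vectors::subjectHits(ov)
  logp <- s$log_p[S4Vectors::queryHits(ov)]
  peaks$tf <- tf
  peaks$condition <- condition
  peaks$score <- as.numeric(tapply(-logp / log(10), grp, max))
  peaks$fold <- as.numeric(tapply(s$fold[S4Vectors::queryHits(ov)], grp, max))
  peaks$n_windows <- as.integer(table(grp))
  sort(peaks)
}

#' Normalize, test and call peaks in one step
#'
#' Convenience wrapper: [quantileNormalize()], [windowTest()] and
#' [callPeaks()] with the experiment's TF and condition labels.
#'
#' @param x a raw \linkS4class{TilingExperiment}.
#' @param windowBp,pMax,foldMin,mergeBp passed to the component steps.
#' @return GRanges of peaks (see [callPeaks()]).
#' @export
callEnrichedPeaks <- function(x, windowBp = 500L, pMax = 1e-4, foldMin = 1.5,
                              mergeBp = 500L) {
  xn <- if (isNormalized(x)) x else quantileNormalize(x)
  stats <- windowTest(xn, windowBp = windowBp)
  callPeaks(stats, pMax = pMax, foldMin = foldMin, mergeBp = mergeBp,
            tf = tfName(x), condition = conditionName(x))
}
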