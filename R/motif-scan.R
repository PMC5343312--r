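## PWM likelihood-ratio motif scanning against a k-th order Markov
## background, JASPAR text PFM parsing, and peak-vs-random motif frequency
## comparison.

BASES <- c("A", "C", "G", "T")

#' Read a JASPAR text position frequency matrix
#'
#' Parses the JASPAR flat-text format: a \code{">name"} header line followed
#' by four rows labeled A, C, G, T with counts, optionally bracketed
#' (\code{A [ 0 3 79 ... ]}). A minimal hand-written reader; no more of the
#' format is supported.
#'
#' @param file path to a JASPAR .pfm/.jaspar text file.
#' @return list with \code{name} and \code{counts} (4 x L matrix, rows
#'   A, C, G, T).
#' @export
readJasparPfm <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1L], ">")) stop("expected '>' header line")
  name <- sub("^>\\s*", "", lines[1L])
  name <- strsplit(name, "\\s+")[[1L]][1L]
  rows <- lines[2:5]
  parsed <- lapply(rows, function(l) {
    base <- toupper(substr(l, 1L, 1L))
    nums <- gsub("[][]", " ", substr(l, 2L, nchar(l)))
    list(base = base, counts = as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
  })
  bases <- vapply(parsed, `[[`, character(1), "base")
  if (!setequal(bases, BASES)) stop("expected four rows labeled A, C, G, T")
  counts <- do.call(rbind, lapply(BASES, function(b)
    parsed[[match(b, bases)]]$counts))
  rownames(counts) <- BASES
  list(name = name, counts = counts)
}

#' Build a PWM from position frequency counts
#'
#' Converts a PFM to a pseudo-count probability matrix:
#' \code{probs[b, j] = (counts[b, j] + pc) / (sum_b counts[b, j] + 4 pc)}.
#'
#' @param counts 4 x L non-negative matrix (rows A, C, G, T) or the list
#'   returned by [readJasparPfm()].
#' @param pseudocount pseudo-count per cell (default 0.5; must be > 0).
#' @param name motif name.
#' @return a \linkS4class{PwmModel}.
#' @examples
#' pfm <- rbind(A = c(10, 0, 0, 5), C = c(0, 10, 0, 5),
#'              G = c(0, 0, 10, 0), T = c(0, 0, 0, 0))
#' buildPwm(pfm, pseudocount = 0.5, name = "toy")
#' @export
buildPwm <- function(counts, pseudocount = 0.5, name = "motif") {
  if (is.list(counts) && !is.matrix(counts)) {
    name <- counts$name %||% name
    counts <- counts$counts
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (ncol(counts) < 4L) stop("motif length must be >= 4")
  rownames(counts) <- BASES
  probs <- sweep(counts + pseudocount, 2L,
                 colSums(counts) + 4 * pseudocount, "/")
  new("PwmModel", name = name, counts = counts,
      pseudocount = pseudocount, probs = probs)
}

seqToCodes <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1L]]
  match(s, BASES)  # non-ACGT -> NA
}

#' Fit a k-th order Markov background
#'
#' Estimates P(base | preceding k-mer) from (k+1)-mer counts with add-one
#' smoothing, so all 4^k contexts are defined. Training concatenates each
#' sequence with its reverse complement, making the model strand-symmetric.
#' Order 0 reduces to the (smoothed) base composition.
#'
#' @param sequences a \link[Biostrings]{DNAStringSet} or character vector
#'   (typically the input-channel tiled regions).
#' @param k Markov order (default 3).
#' @param addRevComp train on both strands (default TRUE).
#' @return a \linkS4class{MarkovBackground}.
#' @export
fitBackground <- function(sequences, k = 3L, addRevComp = TRUE) {
  k <- as.integer(k)
  stopifnot(k >= 0L)
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (!length(sequences) || sum(Biostrings::width(sequences)) == 0L)
    stop("no training sequence provided")
  train <- if (addRevComp)
    c(sequences, Biostrings::reverseComplement(sequences)) else sequences
  baseCnt <- colSums(Biostrings::letterFrequency(train, BASES))
  stationary <- (baseCnt + 1) / sum(baseCnt + 1)
  if (k == 0L) {
    cond <- matrix(stationary, nrow = 1L,
                   dimnames = list("", BASES))
  } else {
    kmerCnt <- colSums(Biostrings::oligonucleotideFrequency(train, width = k + 1L))
    cond <- matrix(kmerCnt, nrow = 4L^k, ncol = 4L, byrow = TRUE)
    ## oligonucleotideFrequency orders k+1-mers lexicographically, so rows
    ## are the 4^k contexts in A<C<G<T order and columns the next base
    cond <- (cond + 1) / (rowSums(cond) + 4)  # add-1 over the 4 next bases
    dimnames(cond) <- list(sortedContexts(k), BASES)
  }
  new("MarkovBackground", order = k, cond = cond,
      stationary = setNames(as.numeric(stationary), BASES),
      trainingBp = as.integer(sum(Biostrings::width(sequences))))
}

sortedContexts <- function(k) {
  if (k == 0L) return("")
  g <- do.call(expand.grid, c(rep(list(BASES), k), KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
  ## expand.grid varies the first factor fastest; lexicographic order needs
  ## the last position fastest, so reverse column roles
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

## Per-window log background probability for all windows of length L.
## The first min(k, L) positions of each window use the stationary
## composition (self-contained window probability: no dependence on flanking
## sequence, which makes minus-strand scores exactly strand-symmetric);
## later positions condition on the k preceding bases (inside the window).
## `codes0` has ambiguous bases replaced by 1 and flagged in `na`: their
## contributions are zeroed here and the affected windows are invalidated by
## the caller, so garbage values cancel instead of poisoning prefix sums.
windowLogBg <- function(codes0, na, background, L) {
  n <- length(codes0)
  k <- background@order
  logStat <- log(background@stationary)
  statPart <- ifelse(na, 0, logStat[codes0])
  starts <- 1:(n - L + 1)
  if (k == 0L) {
    cs <- c(0, cumsum(statPart))
    return(cs[starts + L] - cs[starts])
  }
  ctx <- rep(0, n)
  for (i in seq_len(k)) {
    prev <- c(rep(1L, i), codes0[seq_len(n - i)])
    ctx <- ctx + (prev - 1) * 4^(i - 1)
  }
  cumNa <- c(0L, cumsum(na))
  ctxNa <- c(rep(TRUE, k), (cumNa[(k + 1):n] - cumNa[1:(n - k)]) > 0)
  condPart <- ifelse(na | ctxNa, 0,
                     log(background@cond[cbind(ctx + 1, codes0)]))
  csStat <- c(0, cumsum(statPart))
  csCond <- c(0, cumsum(condPart))
  kk <- min(k, L)
  ## positions start..start+kk-1 from stationary, rest conditional; the
  ## conditional range never reaches positions <= k, so warm-up garbage
  ## cancels in the prefix-sum difference
  (csStat[starts + kk] - csStat[starts]) +
    (if (L > kk) csCond[starts + L] - csCond[starts + kk] else 0)
}

scanOneStrand <- function(codes0, logProbs, logBg) {
  L <- ncol(logProbs)
  nw <- length(codes0) - L + 1L
  sc <- rep(0, nw)
  for (j in seq_len(L))
    sc <- sc + logProbs[cbind(codes0[j:(j + nw - 1L)], j)]
  sc - logBg
}

#' Scan sequences for PWM motif hits
#'
#' Slides the PWM over every window of each sequence and both strands,
#' computing the likelihood ratio LR = P(window | PWM) / P(window |
#' background); windows with LR > \code{lrMin} are reported. The window
#' background probability is self-contained: positions with fewer than k
#' preceding bases inside the window fall back to the background's order-0
#' composition, so LRs do not depend on flanking sequence and minus-strand
#' scores mirror plus-strand scores exactly. Windows containing non-ACGT
#' bases are skipped and tallied.
#'
#' @param sequences \link[Biostrings]{DNAStringSet}, named character vector,
#'   or single character string.
#' @param pwm a \linkS4class{PwmModel}.
#' @param background a \linkS4class{MarkovBackground}.
#' @param lrMin minimum likelihood ratio (default 500, exclusive).
#' @param bothStrands scan the minus strand too (default TRUE).
#' @return \link[GenomicRanges]{GRanges} of hits (1-based coordinates within
#'   each sequence) with metadata columns \code{motif}, \code{lr},
#'   \code{strand}; the number of windows skipped for ambiguous bases is in
#'   \code{metadata()$n_skipped}. Sequences shorter than the motif yield no
#'   hits.
#' @export
scanMotifs <- function(sequences, pwm, background, lrMin = 500, bothStrands = TRUE) {
  stopifnot(is(pwm, "PwmModel"), is(background, "MarkovBackground"))
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is(sequences, "DNAString"))
    sequences <- Biostrings::DNAStringSet(list(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  L <- motifLength(pwm)
  logProbs <- log(pwm@probs)
  ## minus-strand hits score the reverse complement of the window: equivalent
  ## to scanning forward with the reverse-complemented PWM against the
  ## background of the reverse-complemented window
  rcProbs <- pwm@probs[4:1, L:1, drop = FALSE]
  dimnames(rcProbs) <- dimnames(pwm@probs)
  logProbsRC <- log(rcProbs)
  out <- list()
  nSkipped <- 0L
  for (si in seq_along(sequences)) {
    codes <- seqToCodes(sequences[[si]])
    n <- length(codes)
    if (n < L) next
    na <- is.na(codes)
    codes0 <- ifelse(na, 1L, codes)
    cumNa <- c(0L, cumsum(na))
    starts <- 1:(n - L + 1)
    hasN <- (cumNa[starts + L] - cumNa[starts]) > 0
    logBg <- windowLogBg(codes0, na, background, L)
    lrFwd <- exp(scanOneStrand(codes0, logProbs, logBg))
    strandLr <- list("+" = lrFwd)
    if (bothStrands) {
      ## rc window background == background of rc(window) because the model
      ## is trained strand-symmetrically and windows are self-contained
      rcCodes0 <- rev(5L - codes0)
      logBgRC <- rev(windowLogBg(rcCodes0, rev(na), background, L))
      strandLr[["-"]] <- exp(scanOneStrand(codes0, logProbsRC, logBgRC))
    }
    for (std in names(strandLr)) {
      lr <- strandLr[[std]]
      nSkipped <- nSkipped + sum(hasN)
      hit <- which(!hasN & lr > lrMin)
      if (length(hit))
        out[[length(out) + 1L]] <- GRanges(
          names(sequences)[si], IRanges(hit, width = L), strand = std,
          motif = motifName(pwm), lr = lr[hit])
    }
  }
  hits <- if (length(out)) sort(suppressWarnings(do.call(c, out)),
                                ignore.strand = TRUE)
          else GRanges(motif = character(), lr = numeric())
  S4Vectors::metadata(hits)$n_skipped <- nSkipped
  hits
}

#' Compare motif frequency in peaks versus random regions
#'
#' A region "has" the motif when [scanMotifs()] reports at least one hit in
#' it. The two proportions are compared with a two-sided two-proportion
#' test: Fisher's exact test for small samples, the normal approximation
#' (two-sample z) otherwise. Significance is marked at p < 0.00005.
#'
#' @param peakSeqs,randomSeqs \link[Biostrings]{DNAStringSet}s of the peak
#'   and matched random region sequences (equal counts recommended).
#' @param pwm a \linkS4class{PwmModel}.
#' @param background a \linkS4class{MarkovBackground}.
#' @param lrMin hit threshold (default 500).
#' @param exactMax largest pooled region count for the exact test
#'   (default 1000).
#' @param alpha significance marker threshold (default 5e-5).
#' @return list with \code{n_peaks}, \code{n_random},
#'   \code{n_peaks_with_motif}, \code{n_random_with_motif},
#'   \code{pct_peaks_with_motif}, \code{pct_random_with_motif},
#'   \code{p_value}, \code{significant}, \code{method}.
#' @export
motifFrequencyCompare <- function(peakSeqs, randomSeqs, pwm, background,
                                  lrMin = 500, exactMax = 1000L, alpha = 5e-5) {
  n1 <- length(peakSeqs); n2 <- length(randomSeqs)
  if (n1 == 0L || n2 == 0L) stop("both region sets must be non-empty")
  hasMotif <- function(seqs) {
    hits <- scanMotifs(seqs, pwm, background, lrMin = lrMin)
    sum(names(seqs) %in% as.character(seqnames(hits)))
  }
  names(peakSeqs) <- sprintf("p%d", seq_len(n1))
  names(randomSeqs) <- sprintf("r%d", seq_len(n2))
  x1 <- hasMotif(peakSeqs); x2 <- hasMotif(randomSeqs)
  if (n1 + n2 <= exactMax) {
    p <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2L,
                                   byrow = TRUE))$p.value
    method <- "fisher-exact"
  } else {
    ph <- (x1 + x2) / (n1 + n2)
    se <- sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    p <- if (se == 0) 1 else 2 * pnorm(-abs(x1 / n1 - x2 / n2) / se)
    method <- "normal-approximation"
  }
  list(n_peaks = n1, n_random = n2,
       n_peaks_with_motif = x1, n_random_with_motif = x2,
       pct_peaks_with_motif = 100 * x1 / n1,
       pct_random_with_motif = 100 * x2 / n2,
       p_value = min(p, 1), significant = p < alpha, method = method)
}
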