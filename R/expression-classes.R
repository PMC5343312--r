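## Expression response classes: per-timepoint strong/weak induction and
## repression calls from fold change and differential score, combined into
## early/late classes; cross-cell-type sharing classes.

## Per-timepoint call from the +/-13 differential-score and twofold rules.
callAt <- function(fold, diff) {
  if (diff >= 13) {
    if (fold >= 2) "strong-induced" else "weak-induced"
  } else if (diff <= -13) {
    if (fold <= 0.5) "strong-repressed" else "weak-repressed"
  } else "none"
}

#' Classify one gene's IFN-gamma response
#'
#' Applies the differential-score and fold-change rules per timepoint
#' (strong induced: score >= 13 and fold >= 2; weak induced: score >= 13 and
#' fold < 2; strong repressed: score <= -13 and fold <= 0.5; weak repressed:
#' score <= -13 and 0.5 < fold < 1) and derives the class from the earliest
#' timepoint with a call: a 6 h call is early (\code{es-}/\code{ew-}), a
#' first call at 24 or 48 h is late (\code{ls-}/\code{lw-}). Repression calls
#' yield IRG classes. Genes with no call at any timepoint are \code{resISG}
#' when flagged as known ISGs, \code{potISG} when flagged as potential ISGs,
#' and \code{other} otherwise.
#'
#' @param records data.frame for one gene with columns \code{timepoint_h}
#'   (must include 6), \code{fold_change}, \code{diff_score}.
#' @param knownIsg logical, gene is a known ISG (required for a
#'   \code{resISG} assignment).
#' @param potIsg logical, gene is a potential ISG (paralog or TF-bound
#'   promoter; an input flag, not computed).
#' @return a single class label from [GENE_CLASSES].
#' @examples
#' classifyGene(data.frame(timepoint_h = 6, fold_change = 3.1,
#'                         diff_score = 20), knownIsg = TRUE)  # es-indISG
#' @export
classifyGene <- function(records, knownIsg = FALSE, potIsg = FALSE) {
  if (!6 %in% records$timepoint_h)
    stop("records must include the 6 h timepoint")
  records <- records[order(records$timepoint_h), , drop = FALSE]
  calls <- mapply(callAt, records$fold_change, records$diff_score)
  hit <- which(calls != "none")
  if (!length(hit)) {
    if (isTRUE(knownIsg)) return("resISG")
    if (isTRUE(potIsg)) return("potISG")
    return("other")
  }
  first <- hit[1L]
  early <- records$timepoint_h[first] == 6
  switch(calls[first],
    "strong-induced" = if (early) "es-indISG" else "ls-indISG",
    "weak-induced" = if (early) "ew-indISG" else "lw-indISG",
    "strong-repressed" = "ls-IRG",
    "weak-repressed" = "lw-IRG")
}

#' Classify all genes in an expression table
#'
#' @param expr data.frame with columns \code{gene_id}, \code{timepoint_h},
#'   \code{fold_change}, \code{diff_score} and optionally \code{known_isg},
#'   \code{pot_isg} (missing flags default to \code{FALSE}).
#' @return data.frame with one row per gene: \code{gene_id}, \code{class}.
#'   Every gene receives exactly one class.
#' @export
classifyGenes <- function(expr) {
  stopifnot(all(c("gene_id", "timepoint_h", "fold_change", "diff_score") %in%
                  names(expr)))
  ids <- unique(expr$gene_id)
  cls <- vapply(ids, function(g) {
    rec <- expr[expr$gene_id == g, , drop = FALSE]
    classifyGene(rec, knownIsg = isTRUE(rec$known_isg[1L]),
                 potIsg = isTRUE(rec$pot_isg[1L]))
  }, character(1))
  data.frame(gene_id = ids, class = unname(cls))
}

#' Cross-cell-type sharing class
#'
#' Maps the number of cell types (out of a universe of 7) in which a gene is
#' IFN-gamma induced onto the sharing classes: exclusive (\code{Ex}, 1),
#' partially shared (\code{pSh}, 2-4) and ubiquitous (\code{Ub}, 5-7).
#'
#' @param inducedIn character vector of cell-type names the gene is induced
#'   in, or a single integer count.
#' @param universe number of assayed cell types (default 7).
#' @return list with \code{label} (\code{"Ex"}, \code{"pSh"} or \code{"Ub"})
#'   and \code{n} (the count).
#' @examples
#' classifySharing(c("HeLa"))$label        # "Ex"
#' classifySharing(3L)$label               # "pSh"
#' @export
classifySharing <- function(inducedIn, universe = 7L) {
  n <- if (is.numeric(inducedIn)) as.integer(inducedIn) else
    length(unique(inducedIn))
  if (n < 1L) stop("gene is not induced in any cell type")
  if (n > universe) stop("induced in more cell types than the universe")
  label <- if (n == 1L) "Ex" else if (n <= 4L) "pSh" else "Ub"
  list(label = label, n = n)
}
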