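## I/O helpers: TSV probe maps and intensity tables (the synthetic-data
## dialect), BED via rtracklayer, FASTA via Biostrings, and a minimal
## 5-column VCF reader/writer.

#' @importFrom utils read.delim write.table
NULL

#' Write / read a probe map
#'
#' TSV with columns \code{probe_id}, \code{chrom}, \code{start}, \code{end}
#' (0-based half-open, BED-like).
#'
#' @param probes GRanges with a \code{probe_id} column.
#' @param file path.
#' @return \code{readProbeMap}: GRanges (1-based internally).
#' @export
writeProbeMap <- function(probes, file) {
  df <- data.frame(probe_id = probes$probe_id,
                   chrom = as.character(seqnames(probes)),
                   start = start(probes) - 1L, end = end(probes))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeProbeMap
#' @export
readProbeMap <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  gr$probe_id <- df$probe_id
  gr
}

#' Write / read an intensity table
#'
#' TSV with a \code{probe_id} column followed by one column per sample named
#' \code{{channel}_{condition}_rep{i}}.
#'
#' @param x a \linkS4class{TilingExperiment}.
#' @param file path.
#' @param probes probe map GRanges matching the table rows (for reading).
#' @param tf,condition,normalized labels for the reconstructed experiment.
#' @return \code{readIntensities}: a \linkS4class{TilingExperiment}.
#' @export
writeIntensities <- function(x, file) {
  m <- SummarizedExperiment::assay(x, "intensity")
  cond <- conditionName(x)
  prefix <- ifelse(x$channel == "chip",
                   if (is.na(tfName(x))) "chip" else tfName(x), "input")
  df <- data.frame(probe_id = rowRanges(x)$probe_id,
                   setNames(as.data.frame(m),
                            sprintf("%s_%s_rep%d", prefix, cond, x$replicate)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeIntensities
#' @export
readIntensities <- function(file, probes, tf = NA_character_,
                            condition = NA_character_, normalized = FALSE) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(identical(df$probe_id, probes$probe_id))
  m <- as.matrix(df[, -1L, drop = FALSE])
  parts <- strsplit(colnames(m), "_")
  channel <- vapply(parts, `[[`, character(1), 1L)
  replicate <- as.integer(sub("^rep", "", vapply(parts, function(p)
    p[[length(p)]], character(1))))
  channel[channel != "input"] <- "chip"
  tilingExperiment(probes, m, channel = channel, replicate = replicate,
                   tf = tf, condition = condition, normalized = normalized)
}

#' Write intervals as BED6
#'
#' Peaks are written with \code{name = {tf}_{condition}_{k}} and
#' \code{score = round(10 * -log10 p)} capped at 1000 when a \code{score}
#' column is present. Export goes through \pkg{rtracklayer}.
#'
#' @param gr GRanges (peaks, regions or random sites).
#' @param file output .bed path.
#' @return the file path, invisibly.
#' @export
writeBed <- function(gr, file) {
  out <- granges(gr)
  if (!is.null(gr$tf) && !is.null(gr$condition))
    out$name <- sprintf("%s_%s_%d", gr$tf, gr$condition, seq_along(gr))
  else if (!is.null(gr$label))
    out$name <- sprintf("%s_%d", gr$label, seq_along(gr))
  else out$name <- sprintf("site_%d", seq_along(gr))
  out$score <- if (!is.null(gr$score)) pmin(round(10 * gr$score), 1000) else 0L
  rtracklayer::export(out, file, format = "BED")
  invisible(file)
}

#' @rdname writeBed
#' @export
readBed <- function(file) rtracklayer::import(file, format = "BED")

#' Write / read ground-truth planted peaks as BED
#'
#' The enrichment fold is stored in the BED score column (x100 to keep two
#' decimals in the integer field) and the name encodes TF and condition.
#'
#' @param truth GRanges with \code{tf}, \code{condition}, \code{fold}.
#' @param file path.
#' @export
writeTruthBed <- function(truth, file) {
  out <- granges(truth)
  out$name <- sprintf("%s_%s", truth$tf, truth$condition)
  out$score <- round(100 * truth$fold)
  rtracklayer::export(out, file, format = "BED")
  invisible(file)
}

#' Write / read a minimal VCF (CHROM POS ID REF ALT)
#'
#' A deliberately minimal dialect: the five leading VCF columns, tab
#' separated, with \code{##}-prefixed meta lines ignored on input. Not a
#' general VCF parser.
#'
#' @param snps data.frame with \code{id}, \code{chrom}, \code{pos}
#'   (0-based), \code{ref}, \code{alt}.
#' @param file path.
#' @return \code{readSnpVcf}: data.frame in the same layout.
#' @export
writeSnpVcf <- function(snps, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT"), con)
  if (nrow(snps))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s", snps$chrom, snps$pos + 1L,
                       snps$id, snps$ref, snps$alt), con)
  invisible(file)
}

#' @rdname writeSnpVcf
#' @export
readSnpVcf <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "##")]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  f <- strsplit(lines, "\t")
  data.frame(id = vapply(f, `[[`, character(1), 3L),
             chrom = vapply(f, `[[`, character(1), 1L),
             pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
             ref = vapply(f, `[[`, character(1), 4L),
             alt = vapply(f, `[[`, character(1), 5L))
}

#' Write / read the genome FASTA
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param file path.
#' @export
writeGenomeFasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome, file)
  invisible(file)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(file) Biostrings::readDNAStringSet(file)
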