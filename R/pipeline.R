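## Pipeline orchestration: one config object carrying every threshold, a
## default synthetic study emulating the tiling-array design, and a
## simulate -> normalize -> call -> classify -> occupancy -> motifs -> SNPs
## run that produces a report bundle.

#' Construct a pipeline configuration
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @param p_max,fold_min,window_bp,merge_bp peak-caller thresholds
#'   (defaults 1e-4, 1.5, 500, 500).
#' @param proximal_bp proximal/distal cutoff (default 5000).
#' @param lr_min,bg_order motif-scan thresholds (defaults 500, 3).
#' @param snp_cutoff SNP affinity fold-change cutoff (default 1.5).
#' @param ter_threshold TER minimum-enrichment flag (default 2).
#' @param dual_link_bp region-ledger linkage distance (default 500).
#' @param include_pseudogenes include pseudogenes in nearest-gene
#'   assignment (default FALSE).
#' @param n_random number of random control sites (default 0 = match the
#'   peak count).
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, p_max = 1e-4, fold_min = 1.5,
                           window_bp = 500, merge_bp = 500, proximal_bp = 5000,
                           lr_min = 500, bg_order = 3L, snp_cutoff = 1.5,
                           ter_threshold = 2, dual_link_bp = 500,
                           include_pseudogenes = FALSE, n_random = 0L) {
  new("PipelineConfig", params = list(
    seed = as.integer(seed), p_max = p_max, fold_min = fold_min,
    window_bp = window_bp, merge_bp = merge_bp, proximal_bp = proximal_bp,
    lr_min = lr_min, bg_order = as.integer(bg_order),
    snp_cutoff = snp_cutoff, ter_threshold = ter_threshold,
    dual_link_bp = dual_link_bp,
    include_pseudogenes = isTRUE(include_pseudogenes),
    n_random = as.integer(n_random)))
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param file path to a YAML file.
#' @param config a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(file) {
  do.call(pipelineConfig, yaml::read_yaml(file))
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, file) {
  stopifnot(is(config, "PipelineConfig"))
  yaml::write_yaml(config@params, file)
  invisible(file)
}

#' Load the bundled synthetic PWMs
#'
#' Two sharp synthetic position frequency matrices shipped with the package
#' (GAS-like for STAT1, IRF-E-like for IRF1) in JASPAR text format. They
#' are synthetic stand-ins constructed for simulation and testing, not
#' database matrices.
#'
#' @param pseudocount passed to [buildPwm()].
#' @return named list of two \linkS4class{PwmModel}s
#'   (\code{STAT1_synthetic}, \code{IRF1_synthetic}).
#' @export
loadExamplePwms <- function(pseudocount = 0.5) {
  files <- c(STAT1_synthetic = "STAT1_synthetic.pfm",
             IRF1_synthetic = "IRF1_synthetic.pfm")
  lapply(files, function(f)
    buildPwm(readJasparPfm(system.file("extdata", f, package = "isgscape",
                                       mustWork = TRUE)),
             pseudocount = pseudocount))
}

#' Extract region sequences from a segment genome
#'
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param gr GRanges within the genome's segments.
#' @return \link[Biostrings]{DNAStringSet}, one entry per range.
#' @export
extractRegions <- function(genome, gr) {
  seqs <- vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(genome[[as.character(seqnames(gr)[i])]],
                                    start(gr)[i], end(gr)[i])), character(1))
  Biostrings::DNAStringSet(setNames(seqs, sprintf("region_%d", seq_along(gr))))
}

## Consensus instances of the bundled synthetic motifs, and variants with a
## fixed number of mismatches (used to plant gain/loss SNP cases).
GAS_CONSENSUS <- "TTCCGGGAA"
IRFE_CONSENSUS <- "TTTCACTTTC"

mismatched <- function(seq, at, to) {
  substr(seq, at, at) <- to
  seq
}

#' Default synthetic study specification
#'
#' A condensed emulation of the tiling-array study design the pipeline was
#' built for: three multi-hundred-kb segments tiled with 50-mers at 80 bp
#' spacing, three replicates of ChIP and input in basal and induced
#' conditions, gene models spanning all response classes (with pseudogenes),
#' dual STAT1+IRF1 enrichment planted at early strong ISG promoters,
#' isolated IRF1 enrichment at remote positions, a small basal-peak
#' complement, planted GAS-like/IRF-E-like motif instances inside peaks and
#' SNPs inside/outside motifs with known gain/loss effects.
#'
#' @param seed integer root seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
defaultSyntheticSpec <- function(seed = 1L) {
  segments <- data.frame(name = c("segA", "segB", "segC"),
                         length = c(1000000L, 600000L, 400000L))
  classesA <- c("es-indISG", "other", "resISG", "ew-indISG", "es-indISG",
                "other", "ls-indISG", "potISG", "es-indISG", "resISG",
                "lw-indISG", "other", "es-indISG", "ls-IRG", "ew-indISG",
                "other", "ls-indISG", "resISG", "lw-IRG", "other")
  genesA <- data.frame(gene_id = sprintf("geneA%02d", seq_len(20)),
                       segment = "segA", tss = 40000L * (0:19) + 20000L,
                       strand = rep(c("+", "-"), 10), class = classesA,
                       pseudogene = FALSE)
  classesB <- c("es-indISG", "resISG", "other", "ew-indISG", "ls-indISG",
                "other", "es-indISG", "potISG", "lw-indISG", "resISG",
                "ls-IRG", "other")
  genesB <- data.frame(gene_id = sprintf("geneB%02d", seq_len(12)),
                       segment = "segB", tss = 45000L * (0:11) + 30000L,
                       strand = rep(c("+", "-"), 6), class = classesB,
                       pseudogene = FALSE)
  classesC <- c("es-indISG", "other", "resISG", "lw-IRG", "ew-indISG",
                "other", "potISG", "resISG")
  genesC <- data.frame(gene_id = sprintf("geneC%02d", seq_len(8)),
                       segment = "segC", tss = 45000L * (0:7) + 25000L,
                       strand = rep(c("+", "-"), 4), class = classesC,
                       pseudogene = FALSE)
  pseudo <- data.frame(gene_id = sprintf("pseudoA%02d", seq_len(6)),
                       segment = "segA", tss = 150000L * (0:5) + 33000L,
                       strand = "+", class = "other", pseudogene = TRUE)
  genes <- rbind(genesA, genesB, genesC, pseudo)
  genes$known_isg <- genes$class %in% c("es-indISG", "ls-indISG", "ew-indISG",
                                        "lw-indISG", "resISG")
  genes$pot_isg <- genes$class == "potISG"

  es <- genes[genes$class == "es-indISG", ]
  ls <- genes[genes$class == "ls-indISG", ]
  ew <- genes[genes$class == "ew-indISG", ]
  peak <- function(segment, start, width, fold, tf, condition)
    data.frame(segment = segment, start = as.integer(start),
               end = as.integer(start + width), fold = fold, tf = tf,
               condition = condition)
  peaks <- rbind(
    ## dual STAT1+IRF1 at es-indISG promoters (proximal, induced)
    do.call(rbind, lapply(seq_len(nrow(es)), function(i)
      rbind(peak(es$segment[i], es$tss[i] - 900L, 700L, 5, "STAT1", "induced"),
            peak(es$segment[i], es$tss[i] - 500L, 800L, 5, "IRF1", "induced")))),
    ## isolated remote IRF1 at ls-indISG loci (distal, induced)
    do.call(rbind, lapply(seq_len(nrow(ls)), function(i)
      peak(ls$segment[i], ls$tss[i] + 20000L, 800L, 4, "IRF1", "induced"))),
    ## isolated proximal STAT1 at two ew-indISG promoters
    do.call(rbind, lapply(1:2, function(i)
      peak(ew$segment[i], ew$tss[i] + 1500L, 700L, 4, "STAT1", "induced"))),
    ## intergenic isolated IRF1 sites
    peak("segA", 410000L, 800L, 5, "IRF1", "induced"),
    peak("segA", 725000L, 800L, 4, "IRF1", "induced"),
    peak("segB", 260000L, 800L, 6, "IRF1", "induced"),
    peak("segC", 215000L, 800L, 4, "IRF1", "induced"),
    ## basal complement (also enriched after induction)
    peak("segA", 19100L, 700L, 4, "STAT1", "basal"),
    peak("segA", 19500L, 800L, 4, "IRF1", "basal"),
    peak("segB", 260000L, 800L, 4, "IRF1", "basal"),
    peak("segC", 215000L, 800L, 4, "IRF1", "basal"))

  gas1 <- function(at) mismatched(GAS_CONSENSUS, at, "A")
  irfe1 <- function(at) mismatched(IRFE_CONSENSUS, at, "G")
  nes <- nrow(es)
  motifs <- rbind(
    ## consensus instances centred in every dual promoter pair
    data.frame(segment = es$segment, pos = es$tss - 700L,
               strand = rep_len(c("+", "-"), nes), name = "STAT1_synthetic",
               seq = GAS_CONSENSUS),
    data.frame(segment = es$segment, pos = es$tss - 300L,
               strand = rep_len(c("-", "+"), nes), name = "IRF1_synthetic",
               seq = IRFE_CONSENSUS),
    ## consensus IRF-E in the remote ls-indISG peaks
    data.frame(segment = ls$segment, pos = ls$tss + 20300L, strand = "+",
               name = "IRF1_synthetic", seq = IRFE_CONSENSUS),
    ## consensus IRF-E in two intergenic IRF1 peaks
    data.frame(segment = c("segA", "segB"), pos = c(410300L, 260300L),
               strand = "+", name = "IRF1_synthetic", seq = IRFE_CONSENSUS),
    ## one-mismatch IRF-E (still a hit) carrying a restorable SNP
    data.frame(segment = "segA", pos = 725300L, strand = "+",
               name = "IRF1_synthetic", seq = irfe1(5L)),
    ## consensus GAS outside any peak (motif without binding)
    data.frame(segment = "segC", pos = 330000L, strand = "+",
               name = "STAT1_synthetic", seq = GAS_CONSENSUS))

  snps <- rbind(
    ## loss: consensus IRF-E base 5 (C) -> G inside a peak motif
    data.frame(id = "snp_loss_irf1", segment = "segA", pos = 410304L,
               ref = substr(IRFE_CONSENSUS, 5L, 5L), alt = "G"),
    ## gain: one-mismatch IRF-E restored to consensus by the alt allele
    data.frame(id = "snp_gain_irf1", segment = "segA", pos = 725304L,
               ref = "G", alt = substr(IRFE_CONSENSUS, 5L, 5L)),
    ## loss in a GAS motif inside a dual promoter peak
    data.frame(id = "snp_loss_stat1", segment = es$segment[1L],
               pos = es$tss[1L] - 700L + 3L,
               ref = substr(GAS_CONSENSUS, 4L, 4L), alt = "A"),
    ## in a peak but not in any motif
    data.frame(id = "snp_no_motif", segment = "segB", pos = 260600L,
               ref = "N", alt = "A"),
    ## outside all peaks
    data.frame(id = "snp_outside", segment = "segC", pos = 300000L,
               ref = "N", alt = "C"))
  ## placeholder refs resolved to the (deterministic) background base lazily:
  ## use fixed bases consistent with the spliced genome where known
  snps$ref[snps$id == "snp_no_motif"] <- "A"
  snps$alt[snps$id == "snp_no_motif"] <- "G"
  snps$ref[snps$id == "snp_outside"] <- "A"
  snps$alt[snps$id == "snp_outside"] <- "C"

  syntheticSpec(seed = seed, segments = segments,
                plantedPeaks = peaks, plantedMotifs = motifs,
                plantedSnps = snps, geneTemplates = genes)
}

logStage <- function(...) message(sprintf("[isgscape] %s", sprintf(...)))

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates simulate, normalize, peak calling, expression
#' classification, occupancy statistics, motif scanning and the SNP screen
#' from one configuration, with all randomness derived from the config
#' seed. When \code{outDir} is given, stage outputs (FASTA, BED, TSV,
#' report JSON) are written there.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param spec optional \linkS4class{SyntheticSpec}; defaults to
#'   [defaultSyntheticSpec()] seeded from the config.
#' @param outDir optional output directory.
#' @return a report list with elements \code{peaks}, \code{cooccupancy},
#'   \code{ter}, \code{segment_stats}, \code{basal_induced},
#'   \code{profiles}, \code{motifs}, \code{snps}, \code{classes},
#'   \code{params}.
#' @export
runPipeline <- function(config = pipelineConfig(), spec = NULL, outDir = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  p <- config@params
  if (is.null(spec)) spec <- defaultSyntheticSpec(p$seed)

  logStage("simulate: genome + tiling experiment (seed %d)", spec@seed)
  gen <- generateGenome(spec)
  til <- generateTilingExperiment(spec)
  segments <- GRanges(spec@segments$name,
                      IRanges(1L, spec@segments$length))

  logStage("callpeaks: %d experiments", length(til$experiments))
  peakList <- lapply(til$experiments, function(te)
    callEnrichedPeaks(te, windowBp = p$window_bp, pMax = p$p_max,
                      foldMin = p$fold_min, mergeBp = p$merge_bp))
  allPeaks <- suppressWarnings(do.call(c, unname(peakList)))
  stat1Ind <- peakList[["STAT1_induced"]] %||% GRanges()
  irf1Ind <- peakList[["IRF1_induced"]] %||% GRanges()
  inducedPeaks <- suppressWarnings(c(stat1Ind, irf1Ind))

  logStage("classify-genes")
  expr <- generateExpressionTable(spec)
  classes <- classifyGenes(expr)
  genes <- gen$genes
  idx <- match(genes$gene_id, classes$gene_id)
  genes$class <- ifelse(is.na(idx), genes$class, classes$class[idx])

  logStage("occupancy: ledger, random sites, TER, profiles")
  assigned <- assignPeaks(inducedPeaks, genes, proximalBp = p$proximal_bp,
                          includePseudogenes = p$include_pseudogenes)
  ledger <- buildLedger(stat1Ind, irf1Ind, linkBp = p$dual_link_bp)
  cooc <- summarizeCooccupancy(ledger)
  nRandom <- if (p$n_random > 0L) p$n_random else length(inducedPeaks)
  random <- sampleRandomSites(inducedPeaks, segments, n = nRandom,
                              seed = deriveSeed(p$seed, "random-sites"))
  assignedRandom <- assignPeaks(random, genes, proximalBp = p$proximal_bp,
                                includePseudogenes = p$include_pseudogenes)
  ter <- computeTER(assigned, assignedRandom, terThreshold = p$ter_threshold)
  segStats <- segmentStats(inducedPeaks, genes, segments,
                           proximalBp = p$proximal_bp)
  basal <- basalInducedSummary(allPeaks)
  realGenes <- genes[!genes$pseudogene]
  profiles <- list(
    es_indISG = bindingProfile(inducedPeaks,
                               realGenes[realGenes$class == "es-indISG"],
                               segments),
    resISG = bindingProfile(inducedPeaks,
                            realGenes[realGenes$class == "resISG"],
                            segments))

  logStage("motifs: background order %d, LR > %g", p$bg_order, p$lr_min)
  pwms <- loadExamplePwms()
  background <- fitBackground(gen$genome, k = p$bg_order)
  genomeHits <- suppressWarnings(do.call(c, unname(lapply(pwms, function(pwm)
    scanMotifs(gen$genome, pwm, background, lrMin = p$lr_min)))))
  peakSeqs <- extractRegions(gen$genome, inducedPeaks)
  randomSeqs <- extractRegions(gen$genome, random)
  motifCmp <- lapply(pwms, function(pwm)
    motifFrequencyCompare(peakSeqs, randomSeqs, pwm, background,
                          lrMin = p$lr_min))

  logStage("snps: screen %d records", nrow(spec@plantedSnps))
  snps <- spec@plantedSnps
  names(snps)[names(snps) == "segment"] <- "chrom"
  snpScreen <- screenSnps(snps, inducedPeaks, genomeHits, gen$genome, pwms,
                          background, lrMin = p$lr_min, cutoff = p$snp_cutoff)

  report <- list(params = p,
                 truth = til$truth,
                 peaks = allPeaks,
                 ledger = ledger,
                 cooccupancy = cooc,
                 assigned = assigned,
                 random_sites = random,
                 ter = ter,
                 segment_stats = segStats,
                 basal_induced = basal,
                 profiles = profiles,
                 motifs = motifCmp,
                 motif_hits = genomeHits,
                 snps = snpScreen,
                 classes = classes,
                 expression = expr)
  if (!is.null(outDir)) writeReportBundle(report, gen, outDir)
  report
}

#' Write a pipeline report bundle
#'
#' Serializes the report: genome FASTA, peak/region/random-site BED, window
#' and assignment TSVs, and a JSON report of the summary tables.
#'
#' @param report list from [runPipeline()].
#' @param gen list from [generateGenome()] (for the FASTA); may be NULL.
#' @param outDir output directory (created if missing).
#' @return \code{outDir}, invisibly.
#' @export
writeReportBundle <- function(report, gen = NULL, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  if (!is.null(gen)) writeGenomeFasta(gen$genome, fp("genome.fa"))
  if (length(report$peaks)) writeBed(report$peaks, fp("peaks.bed"))
  if (length(report$ledger)) writeBed(report$ledger, fp("regions.bed"))
  if (length(report$random_sites))
    writeBed(report$random_sites, fp("random_sites.bed"))
  write.table(report$assigned, fp("peak_assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$ter, fp("ter.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$segment_stats, fp("segment_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$classes, fp("gene_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- list(params = report$params,
                  cooccupancy = report$cooccupancy,
                  basal_induced = report$basal_induced,
                  motifs = report$motifs,
                  snp_counts = as.list(report$snps$counts),
                  n_peaks = length(report$peaks),
                  n_regions = length(report$ledger))
  jsonlite::write_json(summary, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outDir)
}
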