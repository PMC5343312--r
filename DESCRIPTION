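Package: isgscape
Title: STAT1/IRF1 Enhancer Occupancy Analysis Around Interferon-Stimulated Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing transcription-factor occupancy around
    interferon-stimulated genes (ISGs) from ChIP-chip tiling-array data:
    quantile normalisation and Wilcoxon rank-sum sliding-window peak calling,
    classification of IFN-gamma expression responses into early/late and
    strong/weak classes, proximal/distal and isolated/dual co-occupancy
    statistics with matched random controls and TF enrichment ratios (TER),
    PWM likelihood-ratio motif scanning against a k-th order Markov
    background, and scoring of SNP allele effects on binding motifs. Includes
    a synthetic-data generator that emulates the tiling-array design (50-mer
    probes, ~80 bp spacing, replicated ChIP/input channels) with planted
    enrichment regions, motifs and SNPs for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: ChIPchip, PeakDetection, MotifAnnotation, Transcription,
    GeneRegulation, Software
RoxygenNote: 7.3.3
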