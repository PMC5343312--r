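---
title: "Methods: STAT1/IRF1 occupancy analysis around interferon-stimulated genes"
author: "isgscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STAT1/IRF1 occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isgscape)
```

# Scientific background

Interferon gamma (IFN-γ) signaling activates STAT1, which together with the
secondary factor IRF1 occupies promoters and remote enhancers of
interferon-stimulated genes (ISGs). `isgscape` implements a complete
tiling-array analysis of this system: probe-level ChIP/input intensities are
normalized and tested for local enrichment, enriched intervals are merged
into peaks, peaks are related to genes classified by their expression
response, co-occupancy of the two factors is summarized as isolated/dual
regions, binding is compared against matched random controls through the TF
enrichment ratio (TER), binding motifs are mapped by PWM likelihood ratios
against a Markov background, and SNPs are scored for their predicted effect
on motif strength. A synthetic-data module generates every input with known
ground truth, which is how the pipeline is validated end to end.

# Peak calling

## Model and procedure

Raw intensities from replicated ChIP and input arrays are quantile
normalized jointly (all columns forced onto the per-rank column means; ties
receive the mean of the tied ranks' reference values). For every probe we
form a window of ± 250 bp around the probe center (500 bp total, matching
the chromatin fragment size), pool all replicate values of the probes whose
centers fall inside the window, and test ChIP > input with a one-sided
Wilcoxon rank-sum test. Windows with p < 1e-4 and mean(ChIP)/mean(input) ≥
1.5 are kept; passing window spans within 500 bp of each other are merged
into peaks. No multiple-testing correction is applied — the raw p < 1e-4
filter is the procedure's operating point, and users should treat peak
counts accordingly.

## Numerical choices

* For pooled sample sizes n₁+n₂ ≤ 12 the rank-sum p-value is computed by
  exhaustive enumeration over all labelings of the pooled mid-ranks, which
  remains exact under ties. Larger windows (the normal case: ~7 probes × 3
  replicates per group) use the normal approximation with mid-ranks,
  tie-corrected variance and a 0.5 continuity correction. The continuity
  correction makes the tail slightly conservative, which is the safe
  direction for a raw-p filter; on null simulations with 10⁵ windows the
  observed per-window rate at p < 1e-4 is below 5 × 10⁻⁴ (the windows share
  probes, so neighbouring tests are strongly correlated).
* Probe membership in a window is decided by the probe's center. Window
  fold is the ratio of pooled means; the fold filter is applied per window,
  before merging, which is the conservative reading when a peak's flanks
  are weak.
* Peak score is the best −log₁₀ p among contributing windows, computed on
  the log scale so that extreme windows do not underflow.

# Expression response classes

A gene's response at each timepoint (6, 24, 48 h) is called from its fold
change and the array platform's differential score, treated as an opaque
signed statistic with the ±13 operating threshold: strong induction means
score ≥ 13 and fold ≥ 2; weak induction score ≥ 13 and fold < 2; strong
repression score ≤ −13 and fold ≤ 0.5; weak repression score ≤ −13 and
0.5 < fold < 1. The class is determined by the earliest timepoint with a
call (6 h → early, first call at 24/48 h → late). Genes with no call are
resistant ISGs when flagged as known ISGs, potential ISGs when flagged as
such (an input annotation, not computed from homology), and "other"
otherwise. Because the class vocabulary has no early repressed class,
repression calls are always assigned to the late IRG classes; a 6 h
repression call (not observed in practice) would land there too.
Cross-cell-type sharing maps the number of cell types with induction (out
of 7) onto exclusive (1), partially shared (2–4) and ubiquitous (5–7).

# Occupancy statistics

* **Nearest-gene assignment.** Distance is measured from the peak center to
  the TSS; a peak is proximal when the distance is ≤ 5000 bp (inclusive).
  Ties are broken by the lexicographically smaller gene identifier, and
  pseudogenes are excluded unless requested — both conventions matter when
  reproducing per-segment proximal fractions with and without pseudogenes.
* **Region ledger.** STAT1 and IRF1 peaks are linked into regions when they
  overlap or lie within 500 bp (the merge window); regions are labeled
  isolated-STAT1 / isolated-IRF1 / dual. A strict-overlap mode
  (`linkBp = 0`) is exposed for sensitivity analysis. Dual shares of each
  TF's peaks are reported as (number of dual regions) / (number of TF
  peaks), which is the arithmetic behind the published ledger shares.
* **Random controls.** Matched random sites are length-matched 1:1 to the
  real peaks (cycled if more are requested), allocated to segments
  proportionally to the real per-segment peak counts (largest-remainder
  rounding), and rejection-sampled until they do not overlap any real peak.
* **TER.** For each (gene class, proximal/distal) cell, TER is the percent
  of TF sites in the cell divided by the percent of random sites in the
  same cell; cells with observed but no random support are flagged
  infinite, never replaced by a number. The conventional minimum-enrichment
  flag is TER > 2.
* **Binding profiles.** 401 windows of 1 kb span TSS ± 200 kb, window 0
  centered on the TSS and orientation following gene strand; a peak counts
  in the window containing its center. Windows whose genomic span leaves
  the gene's tiled segment are missing, not zero, and are excluded from
  averaging — this matters for genes near segment edges.
* **Report rounding** follows the conventions of the summaries the numbers
  feed: percentages to integers, ratios and densities to one decimal; raw
  fractions are always retained alongside.

# Motif scanning

PFMs (JASPAR text format) are converted to probability matrices with a
pseudo-count of 0.5 per cell (exposed as a parameter). The background is a
k-th order Markov model (default k = 3) estimated from training sequence by
(k+1)-mer counting with add-one smoothing, trained on both strands so the
model is strand-symmetric. A window's likelihood ratio is
P(window | PWM) / P(window | background), and positions with LR > 500 are
hits.

The window background probability is *self-contained*: the first
min(k, L) positions of a window use the background's order-0 composition
and later positions condition on the preceding bases inside the window.
This choice has two consequences we consider essential: the LR of a window
does not depend on any sequence outside it, and minus-strand scores are
*exactly* the mirror of plus-strand scores (scanning a reverse complement
yields mirrored hits with identical LRs). An alternative convention that
conditions on the k bases left of the window would tie scores to flanking
sequence and break exact strand symmetry; it would also need an arbitrary
fallback at sequence starts. The two conventions differ only in the first k
positions of each window and converge as the background approaches
uniformity. Windows containing non-ACGT bases are skipped and tallied.

Motif frequencies in peak regions versus matched random regions are
compared with a two-sided two-proportion test: Fisher's exact test up to
1000 pooled regions, a two-sample normal approximation beyond; the
significance marker is p < 0.00005.

# SNP effect scoring

For each SNP we extract ± 50 bp of context (independently truncated at
segment edges), build the reference and variant sequences differing only at
the SNP base, and score each allele as the maximum hit LR among windows
covering the SNP position, on either strand. An allele with no overlapping
window above the LR threshold scores 0 (the "NULL" convention). The fold
change is LR(variant)/LR(reference) when the reference scores, and the
verdict is gain at fold ≥ 1.5 or NULL→scored, loss at fold ≤ 1/1.5 or
scored→NULL, null-both when neither allele scores, neutral otherwise. The
cutoff is symmetric by construction, so swapping alleles inverts the fold
change exactly and exchanges gain and loss — a property the tests assert.
The screen runs SNPs through two filters before scoring: inside a called
peak, then covered by a motif hit in the reference genome; stage counts are
reported and are non-increasing. A SNP that would create a motif where the
reference has none is invisible to the screen (no reference hit to overlap)
but can be scored directly with `scoreAllelePair()`.

# Synthetic data

The generator emulates the tiling-array study design: multi-hundred-kb
segments tiled with 50-mers at 80 bp spacing, three biological replicates
of ChIP and input in basal and induced conditions, with quadruplicate spots
emitted pre-averaged (one value per probe per replicate, as the analysis
consumes them). Probe intensities follow a multiplicative lognormal model:
each probe draws a baseline log₂ intensity from N(10, 1) shared by all
arrays of an experiment, and every array value multiplies the baseline by
independent lognormal noise with sd 0.25 in log₂ units. Probes overlapping
a planted peak of the matching TF and condition are additionally multiplied
by the peak's enrichment fold, so the expected log₂ ChIP/input ratio over a
planted fold-4 peak is 2. The lognormal form keeps log-ratios Gaussian,
which is the standard behaviour of two-channel array noise; the scale and
noise magnitude are the package's own calibration (chosen once, before any
validation, so that a fold-4 peak covering eight probes is comfortably but
not trivially detectable) since no physical intensity scale is prescribed
for the simulated platform.

Genomes are i.i.d. uniform A/C/G/T with declared motif instances spliced in
verbatim (reverse-complemented on the minus strand) and SNP reference bases
forced, so planted ground truth is exact. Expression time courses are drawn
uniformly from within the acceptance region of the declared class, making
the generator/classifier round trip a sharp test. What the generator does
*not* model — cross-hybridization, GC and dye bias, repeat content,
correlated probe noise, fragment-level smearing of peak edges — bounds what
passing tests show about real arrays: they validate the statistics and
bookkeeping, not robustness to platform artefacts.

The default study (`defaultSyntheticSpec()`) uses three segments of 1, 0.6
and 0.4 Mb with 40 genes spanning all nine response classes plus six
pseudogenes, dual STAT1+IRF1 enrichment at every early strong ISG promoter,
remote isolated IRF1 sites, a small basal complement, planted GAS-like and
IRF-E-like instances inside peaks, and five SNPs with known effects. The
two bundled PFMs are synthetic stand-ins constructed for this purpose (97:1
count ratio per column), sharp enough that a single mismatch still scores
but two do not.

# Validation design and problem sizes

The test-suite exercises every operation against independent oracles:
exhaustive rank-sum enumeration (all labelings, up to 924), a term-by-term
likelihood product over all 4⁶ hexamers, hypergeometric enumeration for the
exact two-proportion test, and planted ground truth for the caller, the
motif scanner and the SNP screen. Calibration uses a null genome yielding
just over 10⁵ windows, and recovery uses 60 planted fold-4 peaks across 20
seeded genomes; published ledger decompositions (230 regions; 56:16 MHC
sites; 2/92 and 28/196 basal/induced counts; 95/375 ISGs over 16 Mb) are
reconstructed in code and pushed through the summary operations. These
sizes were chosen to give each statistic enough support (10⁵ windows bounds
a 5 × 10⁻⁴ rate estimate well below its threshold) while keeping a full run
in the tens of seconds.

# Known limitations

* The raw ChIP-chip data behind the original study are not available, so
  absolute peak counts (92 STAT1 / 196 IRF1 and quantities derived from
  them) are reproduced through their printed decompositions, not re-derived
  from hybridization signal.
* The differential score is consumed as given; the platform's formula for
  it is not reimplemented.
* The exact linkage rule that produced the published 230-region ledger is
  not stated; the 500 bp linkage reproduces its arithmetic and a
  strict-overlap mode is provided, but other rules are conceivable.
* The two-proportion "probability test" is implemented as Fisher's exact
  test with a normal fast path; the original function is not named.
* Pipeline orchestration is an R API (`runPipeline()` from a YAML-backed
  `PipelineConfig`), not a shell executable; all stages are exported
  functions and can be driven individually.
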