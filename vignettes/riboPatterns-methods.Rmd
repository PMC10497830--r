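---
title: "riboPatterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboPatterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery inside `riboPatterns`,
the assumptions it rests on, the tunable parameters that matter, and the
design decisions that were genuinely open. Everything operates in
transcript coordinates: 0-based, half-open intervals on the spliced
transcript, 5'→3', with the transcript partitioned into 5'UTR / CDS /
3'UTR. We never touch genome space; multi-mapping resolution and alignment
are upstream concerns, and footprints arrive as pre-resolved
transcript-space intervals.

## P-site offsets and periodicity

An elongating ribosome protects a footprint whose 5' end sits a fixed
distance upstream of the P-site codon — canonically 12 nt for 28-30 nt
fragments. `estimateOffsets()` recovers this distance per read length from
a start-codon metagene: the histogram of footprint 5' ends relative to
annotated CDS starts over a window of [−40, +20] nt. Initiating ribosomes
pause on the start codon, so each read-length class shows a 5'-end peak at
minus its offset.

Parameters and defaults:

- `window = c(-40, 20)` nt — wide enough to see the initiation peak and
  enough background to judge it.
- Peak search is restricted to offsets 6-18 nt for 26-32 nt fragments
  (plausible elongating-ribosome geometry); other lengths — e.g. the 21-nt
  short-fragment class — search the full upstream half of the window,
  including offset 0.
- Quality rule: the peak must carry at least `peakFold = 2` times the mean
  window signal and at least `minReadsForOffset = 100` reads must fall in
  the window; otherwise the canonical 12 nt is used, flagged `"default"`
  or `"insufficient"`. Ties break toward the smaller offset
  (deterministically), flagged `"tie"`.

`buildPsiteTracks()` then adds one count at `start + offset(length)` per
read; `frameProfile()` summarizes a region's counts by codon frame
(frame f collects positions with `(i − region_start) mod 3 == f`), ties
broken toward the lowest frame. E/P/A sites are ±3 nt around the P-site
in nucleotide space and are mapped to the codon containing each position;
site positions outside the CDS are excluded from codon occupancy, since
codon usage is only defined over the CDS.

## The multitaper periodicity test

A translated region shows 3-nt periodicity: a spectral line at f = 1/3
cycles per nucleotide. `multitaperTest()` implements the Thomson
multitaper estimate with discrete prolate spheroidal (Slepian) tapers,
computed from the standard symmetric tridiagonal commuting matrix, with
time-bandwidth `NW = 3` and `K = 5` tapers — the textbook configuration,
small enough to work on 60-nt windows. The harmonic F statistic at
f = 1/3,

$$F = \frac{(K-1)\,|\hat\mu|^2 \sum_k U_k(0)^2}{\sum_k |y_k - \hat\mu U_k(0)|^2},$$

is referred to an F(2, 2K−2) null; `y_k` are the eigencoefficients at the
test frequency and `U_k(0)` the taper DC values. Constant (including
all-zero) coverage carries no evidence and returns p = 1.

One numerical subtlety: the *averaged* multitaper spectrum smooths a line
over its bandwidth NW/n, so its argmax over a frequency grid can sit
anywhere inside a plateau of width ~2NW/n around the true line (for a
99-nt period-3 track the plateau argmax landed at 0.344 rather than
0.333). The reported dominant frequency `fStar` is therefore read from
the zero-padded plain periodogram, which keeps line positions sharp, while
the significance test keeps the multitaper eigencoefficients. Tests
verify the engine against an independent harmonic-regression F-test and
against plain DFT argmaxes on pure periodic inputs.

## uORF/dORF calling

`callUtrOrfs()` scans a UTR with 60-nt windows stepped by 15 nt (uORFs
are of the order of 100 nt, and the window must resolve shorter ones; the
shortest scannable region is 30 nt). Windows with fewer than 10 P-sites
or fewer than 5 covered positions are not testable — a handful of reads
cannot evidence translation. Two guards control false calls from sparse
random background coverage:

- `alpha` is applied as a Benjamini-Hochberg FDR level across all
  testable windows of a scan, not per window. At a per-window 0.05 with
  ~8 windows per UTR, essentially every third clean UTR would otherwise
  produce a call.
- A merged region must be frame-coherent: the dominant frame must carry at
  least half the region's signal. Periodic translation concentrates
  P-sites in one frame; random background does not.

Both guards cost nothing on genuine signal (a programmed uORF's window p
is ~1e-8). Contiguous significant windows merge into one call; its start
is the first covered in-frame position, its frame the dominant frame of
the merged region relative to the UTR start. Transcripts whose UTR
annotation is overlapped by another isoform's CDS are excluded from
scanning via the `utr_cds_overlap` annotation flag — a periodic signal
there would be main-ORF contamination, not an independent ORF.

`inferStartCodon()` searches a 60-nt area centred on the periodicity
start (the wording "an area of 60 nt around the start" is ambiguous
between centred and anchored; centred is implemented). Any ATG in the
window wins regardless of frame; otherwise the near-cognate start codon
(CTG, GTG, TTG, ACG, ATT, ATC, ATA, AGG, AAG) in the call's frame nearest
the start is chosen; with no candidate the call is kept with start
`"unknown"`. No stop codon or complete ORF structure is required — calls
are defined by periodicity, not by annotation. `filterOrfCalls()` retains
uORFs only when they start strictly more than 20 nt upstream of the
canonical start, so a true periodicity can be established before the main
ORF; dORFs are not distance-filtered. Overlapping uORFs within one merged
region are reported as a single call.

## Stall sites, frameshifts, disomes, artifacts

`detectStallSites()` first drops transcripts with fewer than 10 total
P-sites (the abundance floor used throughout), then computes μ and σ over
the merged per-nucleotide CDS coverage of all retained transcripts —
zeros included, which dominates real tracks and keeps the threshold
conservative — and reports positions whose count exceeds μ + 4σ. The
first and last 5 codons of each CDS are masked: initiation and
termination pausing are real and strong but are not elongation stalls.
One site is reported per (transcript, codon).

Whether the 4σ rule should apply to raw or per-transcript-normalized
coverage is genuinely open; raw merged coverage is the default, and
`normalize = "per-transcript"` divides each transcript's CDS coverage by
its own mean first, making the threshold insensitive to expression
differences — preferable when library composition is heterogeneous (a
highly expressed transcript's ordinary coverage can otherwise exceed a
global threshold, and an expression gap inflates σ).

Around each site, `detectFrameshift()` compares dominant frames of the
60-nt halves upstream and downstream: a −1 event shows
`down == (up − 1) mod 3` with both dominant-frame fractions ≥ 0.5 (the
fraction cutoff is ours; an unambiguous register seems the minimal
requirement); halves with fewer than 10 P-sites yield no call.
`detectDisome()` looks for a second super-threshold position within
±60 nt, excluding ±2 nt around the site itself. `flagArtifacts()` mirrors
the stall rule on the matched RNA coverage: a site whose surrounding
(±3 nt) RNA coverage also exceeds the RNA track's μ + 4σ is an
over-sequenced fragment, retained in output but excluded from downstream
comparative statistics.

Codon occupancy ratios pair replicates by sorted sample order (the ratio
definition indexes replicates without defining a pairing); the per-codon
test is a two-sample Student's *t* on the normalized occupancies, with
ratios reported alongside — testing occupancies and reporting ratios
covers both readings of an ambiguous formula. Degenerate inputs (zero
pooled variance) give p = 1 when the means agree and a flagged NA when
they do not.

## Differential translation efficiency

TE is footprint abundance relative to mRNA abundance; its change between
conditions is a modality × condition interaction. Rather than delegating
to an external differential-expression package, each gene is fit with one
negative-binomial GLM,

$$\log \mu = \beta_0 + \beta_m\,\text{[ribo]} + \beta_c\,\text{[cond2]}
  + \beta_{mc}\,\text{[ribo × cond2]} + \log s_j,$$

with `te_lfc = β_mc / log 2`. Choices that matter:

- Size factors are median-of-ratios, computed per modality — ribosome
  profiling and RNA-seq are different protocols and must be depth-
  normalized separately.
- Dispersion is per-gene method-of-moments on normalized counts, averaged
  over the four modality × condition groups, floored at 1e-4 and capped
  at 10; no shrinkage. Adequacy is demonstrated, not assumed: on a
  2000-gene null at n = 3, μ ≈ 200, dispersion 0.1, the fraction of genes
  with p < 0.05 is ~0.058, and the mean estimated `te_lfc` for genes
  simulated at 1.5 is within 0.1 of the truth.
- The Wald statistic of the interaction is referred to a *t* distribution
  on the residual degrees of freedom (N − 4) rather than the normal: with
  3 replicates per group the normal reference is visibly anticonservative.
- Significance uses the unadjusted p < 0.05 together with
  |log2FC| ≥ 0.65; BH q-values are reported but not gated on, matching
  the cutoff convention of the analyses this package supports. The
  classification summary reports the share of significant genes that are
  under- vs over-translated.

A caveat demonstrated by the recovery tests: median-of-ratios absorbs
fold changes shared by a large fraction of genes, so TE shifts are
identifiable only relative to a mostly-null background (at 10% deregulated
genes the size-factor contamination already biases estimates by ~0.1
log2 units; at 5% it is negligible). This is inherent to global-scaling
normalization, not to this implementation.

## Subset statistics and prioritization

`teCdfComparison()` compares the TE log2FC distribution of a
feature-defined gene subset (stalled, uORF- or dORF-carrying) against the
complement with a two-sided Wilcoxon rank-sum test — exact when both
groups have ≤ 20 untied values, otherwise the normal approximation with
tie and continuity corrections — and exports CDF points for plotting.
`featureShareTest()` compares per-replicate feature shares between
conditions with Student's *t*, pairing replicates by position.

`geneSetEnrichment()` offers two modes on a user-supplied GMT:
hypergeometric over-representation of significant TE genes (default) and
a rank-sum mode on the set's TE log2FC against the complement — the two
natural readings of uploading "gene names and log2FC" to an enrichment
service. Directionality is the sign of the set's mean TE log2FC, and the
combined score `−log10(p) × direction` is defined only for sets with more
than 5 universe members.

The importance score combines four evidence components. As printed, the
formula's precedence and the sign of its fold-change term are ambiguous;
the default reading,

$$S = -\log_{10} p_{TE} + (-\log_{10} p_{pathway}) \cdot |log2FC_{TE}|
  \cdot c_g,$$

is the one that is monotone in every component — a literal left-to-right
product with a signed fold change would rank strongly *down*-translated
genes in significant pathways below unremarkable ones, which contradicts
the score's purpose. The literal signed form stays available via
`mode = "literal"`. A gene's pathway is its most significant containing
pathway below `pathwayAlpha = 0.05`; genes in no significant pathway take
p = 1 and the term vanishes. `c_g` is the gene's degree over total network
edges (so Σ c_g = 2 over all genes).

## The simulator: what it emulates and what it does not

`simulationConfig()` describes a two-condition experiment — two conditions
× ≥ 2 replicates, negative-binomial (gamma-Poisson) counts with shared
dispersion 0.1, lognormal transcript abundances (σ_log = 0.8), sequencing
yield proportional to abundance × target length, a footprint length mix
of 40/35/20/5% for 28/29/30/21 nt with offsets +12/+12/+12/+9, in-frame
P-site probability 0.9 (the two off-frame positions share the rest), a
5-fold initiation peak on the start codon, 1% non-periodic UTR background,
and programmed stalls (multiplicative codon folds), frameshifts (register
switches), disomes (a paired stall 60 nt upstream), periodic uORFs/dORFs
at 20% of CDS depth, and per-gene TE log2FC applied to the second
condition's ribosome means only. The seed is mandatory; there is no hidden
randomness, and a fixed seed gives bit-identical outputs.

What it does **not** emulate — and what passing tests therefore cannot
show about real data: sequencing errors and soft-clipping, UMI
duplication, nuclease sequence bias at fragment ends, isoform mixtures
mapping to shared transcripts, genome-space multimapping, codon-specific
dwell-time variation beyond programmed stalls, and biological covariance
between RNA and ribosome changes. Recovery results on simulated data are
necessary, not sufficient, evidence for performance on real libraries.

## Problem sizes and runtimes

The test suite validates at desk scale: offset recovery over 20 seeds at
5 × 10⁴ reads/library; stall sensitivity/specificity at 110 transcripts ×
10⁴ reads each; TE calibration on 2000-gene nulls and a 4000-gene
recovery; rank-sum calibration over 2000 null replicates; and an
end-to-end two-condition experiment (50 transcripts, seed 7) recovering
programmed stall/uORF/dORF gene sets at Jaccard ≥ 0.8. The full suite
runs in about a minute on one CPU.

## Known limitations

- Offset estimation needs a visible initiation peak; libraries treated
  with initiation inhibitors (harringtonine/LTM) violate the metagene
  geometry assumption and will fall back to the canonical 12 nt.
- The stall threshold is a global sample-level rule; per-transcript
  normalization is offered but dwell-time-style per-codon models are out
  of scope.
- ORF calls carry no stop-codon or length annotation beyond the periodic
  region; overlapping uORFs in one region are merged.
- The NB interaction model uses no dispersion shrinkage; with fewer than
  3 replicates its dispersion estimates are noisy and p-values
  correspondingly approximate (calibration is verified at n = 3).
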