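## Central S4 containers. All coordinates are 0-based, half-open, in
## transcript space (5'->3', strand already resolved).

#' TranscriptomeIndex: transcript sequences plus region annotation
#'
#' Holds transcript DNA sequences together with the 5'UTR/CDS/3'UTR
#' partition of each transcript and a gene-to-transcript map. Every
#' downstream computation works in this transcript coordinate system.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by transcript id.
#' @slot anno data.frame with columns `transcript_id`, `gene_id`, `biotype`,
#'   `utr5_len`, `cds_len`, `utr3_len` (and optionally `utr_cds_overlap`,
#'   a logical marking transcripts whose UTR annotation is overlapped by a
#'   CDS of another isoform; such transcripts are skipped by ORF scanning).
#' @slot geneMap named list: gene id -> character vector of transcript ids.
#' @slot skipped data.frame recording transcripts rejected at load time
#'   (columns `transcript_id`, `reason`).
#' @export
setClass("TranscriptomeIndex",
  slots = c(sequences = "DNAStringSet", anno = "data.frame",
            geneMap = "list", skipped = "data.frame"))

setValidity("TranscriptomeIndex", function(object) {
  a <- object@anno
  need <- c("transcript_id", "gene_id", "biotype",
            "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(a)))
    return(paste("anno must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$transcript_id))
    return("duplicated transcript ids")
  if (!identical(names(object@sequences), a$transcript_id))
    return("sequence names must match anno$transcript_id in order")
  tot <- a$utr5_len + a$cds_len + a$utr3_len
  if (length(object@sequences) && !all(tot == Biostrings::width(object@sequences)))
    return("utr5_len + cds_len + utr3_len must equal sequence length")
  if (any(a$cds_len > 0 & a$cds_len %% 3L != 0L))
    return("cds_len must be divisible by 3")
  if (length(object@geneMap) &&
      !all(unlist(object@geneMap) %in% a$transcript_id))
    return("geneMap refers to unknown transcript ids")
  TRUE
})

#' FootprintSet: raw footprint (or RNA fragment) intervals on transcripts
#'
#' @slot sampleId single character sample identifier.
#' @slot condition single character condition label (may be `NA`).
#' @slot modality `"ribo"` or `"rna"`.
#' @slot records data.frame with columns `transcript_id`, `start` (0-based),
#'   `length` (nt, >= 1).
#' @slot nDropped number of input records dropped at load time
#'   (out of bounds or unknown transcript).
#' @export
setClass("FootprintSet",
  slots = c(sampleId = "character", condition = "character",
            modality = "character", records = "data.frame",
            nDropped = "integer"))

setValidity("FootprintSet", function(object) {
  if (!object@modality %in% c("ribo", "rna"))
    return("modality must be 'ribo' or 'rna'")
  r <- object@records
  if (!all(c("transcript_id", "start", "length") %in% names(r)))
    return("records needs transcript_id, start, length")
  if (nrow(r) && (any(r$start < 0L) || any(r$length < 1L)))
    return("start must be >= 0 and length >= 1")
  TRUE
})

#' OffsetTable: P-site offset per footprint read length
#'
#' The offset is the distance (nt) from a footprint's 5' end to the first
#' nucleotide of the P-site codon; canonically 12 nt for 28-30 nt footprints.
#'
#' @slot offsets named integer vector (names = read length in nt).
#' @slot flags named character vector, one of `"ok"`, `"default"`, `"tie"`,
#'   `"insufficient"`.
#' @export
setClass("OffsetTable",
  slots = c(offsets = "integer", flags = "character"))

setValidity("OffsetTable", function(object) {
  if (!identical(names(object@offsets), names(object@flags)))
    return("offsets and flags must share names")
  len <- suppressWarnings(as.integer(names(object@offsets)))
  if (anyNA(len)) return("offset names must be read lengths")
  if (any(object@offsets < 0L | object@offsets >= len))
    return("offsets must satisfy 0 <= offset < read_length")
  TRUE
})

#' PsiteTrackSet: per-transcript P-site count vectors for one sample
#'
#' @slot sampleId,condition,modality as in [FootprintSet-class].
#' @slot tracks named list (by transcript id) of integer vectors, one count
#'   per nucleotide of the transcript.
#' @slot nDropped reads whose P-site fell outside the transcript.
#' @export
setClass("PsiteTrackSet",
  slots = c(sampleId = "character", condition = "character",
            modality = "character", tracks = "list", nDropped = "integer"))

#' CodonOccupancy: normalized per-codon site occupancy for one sample
#'
#' Occupancy of a codon is the summed E-, P- or A-site coverage over all CDS
#' positions carrying that codon, divided by the total over the 64 codons.
#'
#' @slot sampleId sample identifier.
#' @slot site one of `"E"`, `"P"`, `"A"`.
#' @slot fractions named numeric vector over the 64 DNA codons, summing to 1
#'   when any coverage exists.
#' @slot flag `"ok"` or `"no_coverage"`.
#' @export
setClass("CodonOccupancy",
  slots = c(sampleId = "character", site = "character",
            fractions = "numeric", flag = "character"))

setValidity("CodonOccupancy", function(object) {
  if (!object@site %in% c("E", "P", "A")) return("site must be E, P or A")
  if (length(object@fractions) != 64L) return("need all 64 codons")
  if (any(object@fractions < 0)) return("fractions must be >= 0")
  s <- sum(object@fractions)
  if (object@flag == "ok" && abs(s - 1) > 1e-9)
    return("fractions must sum to 1")
  TRUE
})

#' GeneSetCollection: named gene sets (GMT)
#'
#' @slot sets named list of character vectors (unique gene ids, non-empty).
#' @export
setClass("GeneSetCollection", slots = c(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) && is.null(names(object@sets)))
    return("sets must be named")
  if (any(lengths(object@sets) == 0L)) return("empty gene set")
  TRUE
})

#' NetworkGraph: undirected gene-gene interaction network
#'
#' @slot edges data.frame with columns `a`, `b`; each row one undirected
#'   edge with `a < b` lexicographically; no self-loops, no duplicates.
#' @export
setClass("NetworkGraph", slots = c(edges = "data.frame"))

setValidity("NetworkGraph", function(object) {
  e <- object@edges
  if (!all(c("a", "b") %in% names(e))) return("edges needs columns a, b")
  if (nrow(e)) {
    if (any(e$a == e$b)) return("self-loops not allowed")
    if (any(e$a > e$b)) return("edges must be canonical (a < b)")
    if (anyDuplicated(paste(e$a, e$b))) return("duplicate edges")
  }
  TRUE
})

#' SimulationConfig: parameters of the two-condition translatome simulator
#'
#' The simulator emulates a two-condition (e.g. normal vs senescent)
#' ribosome profiling + RNA-seq experiment: negative-binomial counts,
#' length-specific P-site offsets, tunable 3-nt periodicity, a start-codon
#' initiation peak, programmed stall spikes, frameshifts, disome pairs,
#' periodic uORFs/dORFs and known per-gene translation-efficiency shifts.
#'
#' @slot nTranscripts number of protein-coding transcripts.
#' @slot utr5Range,utr3Range integer length ranges (nt) for the UTRs.
#' @slot cdsCodonRange integer range for CDS length in codons (incl. start
#'   and stop codons).
#' @slot nReplicates replicates per condition.
#' @slot conditionNames two condition labels; the first is the reference.
#' @slot meanRiboDepth,meanRnaDepth mean reads per transcript per library.
#' @slot abundanceSdLog log-sd of the lognormal relative transcript
#'   abundances (0 = every transcript at the mean depth).
#' @slot nbDispersion shared negative-binomial dispersion of library counts.
#' @slot periodicityStrength probability that a P-site falls on the first
#'   nucleotide of its codon; the two off-frame positions share the rest
#'   equally. Must lie in [1/3, 1].
#' @slot offsetMap named integer vector read length -> P-site offset (nt).
#' @slot lengthMix named numeric vector read length -> probability.
#' @slot startPeakFold multiplicative occupancy of the initiation codon
#'   (ribosomes pause at the start codon in real libraries).
#' @slot utrBackgroundRate expected non-periodic UTR background P-sites as a
#'   fraction of a transcript's CDS depth.
#' @slot uorfRelDensity expected P-sites in a programmed uORF/dORF as a
#'   fraction of the host transcript's CDS depth.
#' @slot stallSpec data.frame(transcript_id, codon_index, fold): programmed
#'   elongation stalls (codon_index 0-based within the CDS).
#' @slot frameshiftSpec data.frame(transcript_id, position, shift): register
#'   switch of all P-sites downstream of `position` (CDS-relative nt) by
#'   `shift` in {-1, +1}.
#' @slot disomeSpec data.frame(transcript_id, codon_index, fold): a stall at
#'   `codon_index` plus a collided-ribosome stall 60 nt (20 codons) upstream.
#' @slot uorfSpec,dorfSpec data.frame(transcript_id, start, length,
#'   start_codon): programmed periodic ORFs; `start` is UTR-relative (nt).
#' @slot teLfcMap named numeric: gene id -> true TE log2 fold change applied
#'   to the second condition's ribosome counts (RNA left unchanged).
#' @slot seed integer random seed (mandatory; no hidden global randomness).
#' @export
setClass("SimulationConfig",
  slots = c(nTranscripts = "integer",
            utr5Range = "integer", cdsCodonRange = "integer",
            utr3Range = "integer",
            nReplicates = "integer", conditionNames = "character",
            meanRiboDepth = "numeric", meanRnaDepth = "numeric",
            abundanceSdLog = "numeric",
            nbDispersion = "numeric", periodicityStrength = "numeric",
            offsetMap = "integer", lengthMix = "numeric",
            startPeakFold = "numeric", utrBackgroundRate = "numeric",
            uorfRelDensity = "numeric",
            stallSpec = "data.frame", frameshiftSpec = "data.frame",
            disomeSpec = "data.frame",
            uorfSpec = "data.frame", dorfSpec = "data.frame",
            teLfcMap = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  p <- object@periodicityStrength
  if (p < 1 / 3 || p > 1)
    return("periodicityStrength must lie in [1/3, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("an explicit integer seed is required")
  if (!setequal(names(object@lengthMix), names(object@offsetMap)) &&
      !all(names(object@lengthMix) %in% names(object@offsetMap)))
    return("every read length in lengthMix needs an entry in offsetMap")
  if (abs(sum(object@lengthMix) - 1) > 1e-8)
    return("lengthMix must sum to 1")
  if (length(object@conditionNames) != 2L)
    return("exactly two condition names required")
  TRUE
})

#' GroundTruth: the programmed features of a simulated experiment
#'
#' @slot stalls,frameshifts,disomes,uorfs,dorfs data.frames mirroring the
#'   corresponding [SimulationConfig-class] slots, with transcript-space
#'   coordinates resolved.
#' @slot teLfc named numeric: true TE log2FC per gene (0 where unprogrammed).
#' @slot abundance named numeric: relative transcript abundance weights.
#' @export
setClass("GroundTruth",
  slots = c(stalls = "data.frame", frameshifts = "data.frame",
            disomes = "data.frame", uorfs = "data.frame",
            dorfs = "data.frame", teLfc = "numeric",
            abundance = "numeric"))
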