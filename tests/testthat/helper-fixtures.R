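# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures.

# A deterministic hand-built index: one 90-nt transcript with
# utr5=15, cds=60, utr3=15. The CDS starts with ATG, has a CCG at codon
# index 3 and ends with TAA; no internal in-frame stops.
tinyIndexSeq <- function() {
  utr5 <- "GGGAAACCCTTTGGA"                        # 15 nt
  cds <- paste0("ATG", "AAA", "GAA", "CCG", "GGT", "CTG", "TTC", "GAC",
                "CAT", "ATC", "AAG", "GTG", "CCA", "ACC", "GGA", "TCC",
                "GCT", "TGG", "CGA", "TAA")        # 20 codons = 60 nt
  utr3 <- "TTTCCCAAAGGGTAC"                        # 15 nt
  paste0(utr5, cds, utr3)
}

tinyIndex <- function(biotype = "protein_coding") {
  dirn <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dirn, "tx.fa")
  an <- file.path(dirn, "tx.tsv")
  writeLines(c(">tx1", tinyIndexSeq()), fa)
  write.table(data.frame(transcript_id = "tx1", gene_id = "gene1",
                         biotype = biotype, utr5_len = 15, cds_len = 60,
                         utr3_len = 15),
              an, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(loadTranscriptome(fa, an))
}

# index built directly from sequences + annotation (no files)
indexFromSeqs <- function(seqs, anno) {
  dirn <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dirn, "tx.fa")
  an <- file.path(dirn, "tx.tsv")
  writeLines(as.vector(rbind(paste0(">", anno$transcript_id), seqs)), fa)
  write.table(anno, an, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(loadTranscriptome(fa, an))
}

# a PsiteTrackSet built from an explicit list of count vectors
trackSetOf <- function(tracks, sampleId = "s1", condition = "normal",
                       modality = "ribo") {
  new("PsiteTrackSet", sampleId = sampleId, condition = condition,
      modality = modality, tracks = tracks, nDropped = 0L)
}

footprintSetOf <- function(records, sampleId = "s1", condition = "normal",
                           modality = "ribo") {
  new("FootprintSet", sampleId = sampleId, condition = condition,
      modality = modality, records = records, nDropped = 0L)
}

occupancyOf <- function(fractions, sampleId = "s", site = "P") {
  new("CodonOccupancy", sampleId = sampleId, site = site,
      fractions = fractions, flag = "ok")
}

# fractions vector where one codon gets `value` and the rest share evenly
codonFractions <- function(codon, value) {
  codons <- names(Biostrings::GENETIC_CODE)
  f <- setNames(rep((1 - value) / 63, 64), codons)
  f[codon] <- value
  f
}

# simulate a small experiment (transcriptome + libraries) in one call
simExperiment <- function(seed, ...) {
  cfg <- simulationConfig(seed = seed, ...)
  sim <- simulateTranscriptome(cfg)
  libs <- simulateLibraries(sim$index, sim$truth, cfg)
  list(cfg = cfg, index = sim$index, truth = sim$truth, libs = libs)
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# independent oracle: harmonic-regression F-test for a line at frequency f0
periodogramFtest <- function(x, f0 = 1 / 3) {
  n <- length(x)
  t0 <- 0:(n - 1)
  fit <- stats::lm(x ~ cos(2 * pi * f0 * t0) + sin(2 * pi * f0 * t0))
  av <- stats::anova(fit)
  Fst <- sum(av[1:2, "Sum Sq"]) / 2 / av["Residuals", "Mean Sq"]
  stats::pf(Fst, 2, n - 3, lower.tail = FALSE)
}

# independent oracle: exact two-sided rank-sum p by full enumeration
exactRankSumP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

# independent oracle: hypergeometric upper tail by direct summation
hyperTailP <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# a classified TE table with nSig clearly significant genes
mkClassified <- function(n = 100, nSig = 10, lfc = NULL) {
  te <- data.frame(gene_id = sprintf("g%03d", 1:n), rna_lfc = 0,
                   ribo_lfc = 0,
                   te_lfc = if (is.null(lfc)) rep(0, n) else lfc,
                   p_value = c(rep(1e-4, nSig), rep(0.8, n - nSig)),
                   q_value = NA_real_)
  if (is.null(lfc))
    te$te_lfc <- c(rep(1, nSig), rep(0.01, n - nSig))
  classifyTE(te)
}

# independent oracle: classic equal-variance two-sample t
studentTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * stats::pt(-abs(tt), nx + ny - 2))
}
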