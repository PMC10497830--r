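## Internal helpers shared across modules.

# the 64 DNA codons in the conventional order of the standard genetic code
.codons <- function() names(Biostrings::GENETIC_CODE)

.stopCodons <- c("TAA", "TAG", "TGA")

# near-cognate start codons examined when no ATG is found in the window
.nearCognateStarts <- c("CTG", "GTG", "TTG", "ACG", "ATT", "ATC", "ATA",
                        "AGG", "AAG")

# 0-based half-open CDS bounds of one annotation row
.cdsBounds <- function(annoRow) {
  s <- annoRow$utr5_len
  c(start = s, end = s + annoRow$cds_len)
}

# region bounds (0-based half-open) for UTR5/CDS/UTR3
.regionBounds <- function(annoRow, region) {
  u5 <- annoRow$utr5_len; cd <- annoRow$cds_len; u3 <- annoRow$utr3_len
  switch(region,
         UTR5 = c(0L, u5),
         CDS  = c(u5, u5 + cd),
         UTR3 = c(u5 + cd, u5 + cd + u3),
         stop("unknown region: ", region))
}

.annoRow <- function(index, tx) {
  i <- match(tx, index@anno$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", tx)
  index@anno[i, , drop = FALSE]
}

.txLength <- function(index, tx) {
  Biostrings::width(index@sequences)[match(tx, names(index@sequences))]
}

.txSeq <- function(index, tx) {
  as.character(index@sequences[[match(tx, names(index@sequences))]])
}

# codon triplets of a CDS (character vector, length cds_len/3)
.cdsCodons <- function(index, tx) {
  row <- .annoRow(index, tx)
  b <- .cdsBounds(row)
  s <- substr(.txSeq(index, tx), b["start"] + 1L, b["end"])
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

.emptyFootprintRecords <- function() {
  data.frame(transcript_id = character(), start = integer(),
             length = integer(), stringsAsFactors = FALSE)
}

# dominant frame of a count triple; ties broken by lowest frame index
.dominantFrame <- function(frameCounts) {
  which.max(frameCounts) - 1L
}

# two-sample Student t (equal variance) with degenerate-data guard:
# zero pooled variance and equal means -> p = 1; zero variance with
# different means -> p = NA (flagged by callers)
.studentT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    return(list(t = NA_real_, p = NA_real_, flag = "insufficient"))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy < .Machine$double.eps * max(1, mean(c(x, y))^2)) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, p = 1, flag = "degenerate"))
    return(list(t = NA_real_, p = NA_real_, flag = "degenerate"))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, flag = "ok")
}

# Wilcoxon rank-sum: exact when both groups <= 20 and untied, otherwise
# normal approximation with tie correction and continuity correction
.wilcoxonRankSum <- function(x, y) {
  exact <- length(x) <= 20L && length(y) <= 20L &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.readTSV <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
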