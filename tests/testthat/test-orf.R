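test_that("programmed uORFs are recovered with good overlap", {
  uspec <- data.frame(transcript_id = "tx001", start = 10L, length = 60L,
                      start_codon = "ATG")
  s <- simExperiment(seed = 15, nTranscripts = 8, meanRiboDepth = 8000,
                     meanRnaDepth = 100, uorfSpec = uspec)
  fp <- s$libs$ribo[[1]]
  tr <- buildPsiteTracks(fp, estimateOffsets(fp, s$index), s$index)
  calls <- callUtrOrfs(tr, s$index, "UTR5")
  hit <- calls[calls$transcript_id == "tx001", ]
  expect_equal(nrow(hit), 1L)
  # >= 80% overlap with the programmed [10, 70) region
  ov <- max(0, min(hit$end, 70) - max(hit$start, 10))
  expect_gte(ov / 60, 0.8)
  expect_equal(hit$frame, 10L %% 3L)
})

test_that("zero-coverage and CDS-overlapped UTRs yield no calls", {
  # zero-depth configurations warn but still produce (empty) libraries
  expect_warning(
    s <- simExperiment(seed = 16, nTranscripts = 3, meanRiboDepth = 0,
                       meanRnaDepth = 0),
    "zero ribosome depth") |> suppressWarnings()
  empty <- trackSetOf(lapply(setNames(nm = transcriptIds(s$index)),
                             function(tx) {
                               w <- Biostrings::width(
                                 transcriptSeqs(s$index))[
                                   match(tx, transcriptIds(s$index))]
                               integer(w)
                             }))
  expect_equal(nrow(callUtrOrfs(empty, s$index, "UTR5")), 0L)

  # a transcript flagged as CDS-overlapped is excluded from scanning
  uspec <- data.frame(transcript_id = "tx001", start = 10L, length = 60L,
                      start_codon = "ATG")
  s2 <- simExperiment(seed = 15, nTranscripts = 8, meanRiboDepth = 8000,
                      meanRnaDepth = 100, uorfSpec = uspec)
  s2$index@anno$utr_cds_overlap[1] <- TRUE
  fp <- s2$libs$ribo[[1]]
  tr <- buildPsiteTracks(fp, estimateOffsets(fp, s2$index), s2$index)
  calls <- callUtrOrfs(tr, s2$index, "UTR5")
  expect_false("tx001" %in% calls$transcript_id)
})

test_that("programmed dORFs are called in the 3'UTR", {
  dspec <- data.frame(transcript_id = "tx001", start = 15L, length = 60L,
                      start_codon = "ATG")
  s <- simExperiment(seed = 17, nTranscripts = 6, meanRiboDepth = 8000,
                     meanRnaDepth = 100, dorfSpec = dspec)
  fp <- s$libs$ribo[[1]]
  tr <- buildPsiteTracks(fp, estimateOffsets(fp, s$index), s$index)
  calls <- callUtrOrfs(tr, s$index, "UTR3")
  hit <- calls[calls$transcript_id == "tx001", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$kind, "dORF")
  a <- transcriptAnno(s$index)[1, ]
  expect_gte(hit$start, a$utr5_len + a$cds_len)
  expect_equal(hit$distance_to_cds,
               hit$start - (a$utr5_len + a$cds_len))
})

test_that("start codons are inferred by the window rules", {
  # build a transcript whose 5'UTR content is fully controlled
  utr5 <- paste0(strrep("C", 30), "ATG", strrep("C", 57))  # ATG at pos 30
  cds <- paste0("ATG", strrep("AAA", 30), "TAA")
  seqs <- paste0(utr5, cds, strrep("T", 30))
  anno <- data.frame(transcript_id = "tx1", gene_id = "g1",
                     biotype = "protein_coding", utr5_len = 90L,
                     cds_len = 96L, utr3_len = 30L)
  idx <- indexFromSeqs(seqs, anno)
  call <- data.frame(transcript_id = "tx1", kind = "uORF", region = "UTR5",
                     start = 26L, end = 80L, frame = 26L %% 3L,
                     start_codon = NA_character_, start_is_ATG = NA,
                     periodicity_p = 1e-4, distance_to_cds = 64L)
  out <- inferStartCodon(call, idx)
  expect_equal(out$start_codon, "ATG")     # ATG 4 nt downstream of start
  expect_true(out$start_is_ATG)

  # no ATG: in-frame CTG at -6 from the periodicity start is picked
  utr5b <- paste0(strrep("C", 24), "CTG", strrep("C", 63))  # CTG at 24
  idxB <- indexFromSeqs(paste0(utr5b, cds, strrep("T", 30)), anno)
  callB <- call; callB$start <- 30L; callB$frame <- 30L %% 3L
  outB <- inferStartCodon(callB, idxB)
  expect_equal(outB$start_codon, "CTG")
  expect_false(outB$start_is_ATG)

  # nothing but C in the window: unknown, call retained
  idxC <- indexFromSeqs(paste0(strrep("C", 90), cds, strrep("T", 30)), anno)
  outC <- inferStartCodon(callB, idxC)
  expect_equal(outC$start_codon, "unknown")
})

test_that("the >20-nt proximity rule is strict", {
  mkCall <- function(dist) data.frame(
    transcript_id = "tx1", kind = "uORF", region = "UTR5", start = 0L,
    end = 30L, frame = 0L, start_codon = "ATG", start_is_ATG = TRUE,
    periodicity_p = 1e-4, distance_to_cds = as.integer(dist))
  calls <- rbind(mkCall(10), mkCall(20), mkCall(21), mkCall(25))
  f <- filterOrfCalls(calls)
  expect_equal(f$retained$distance_to_cds, c(21L, 25L))
  expect_equal(f$excluded$distance_to_cds, c(10L, 20L))
  expect_true(all(f$excluded$reason == "too_close_to_cds"))
  # dORFs are never distance-filtered
  d <- mkCall(5); d$kind <- "dORF"; d$region <- "UTR3"
  expect_equal(nrow(filterOrfCalls(d)$retained), 1L)
})

test_that("start-codon distributions sum to one per kind", {
  calls <- data.frame(
    transcript_id = paste0("tx", 1:4), kind = "uORF", region = "UTR5",
    start = 0L, end = 30L, frame = 0L,
    start_codon = c("ATG", "ATG", "ATG", "CTG"),
    start_is_ATG = c(TRUE, TRUE, TRUE, FALSE),
    periodicity_p = 1e-4, distance_to_cds = 30L)
  tb <- startCodonDistribution(calls)
  expect_equal(tb$fraction[tb$start_codon == "ATG"], 0.75)
  expect_equal(tb$fraction[tb$start_codon == "CTG"], 0.25)
  expect_equal(nrow(startCodonDistribution(calls[0, ])), 0L)
  # only dORFs present: no uORF rows
  d <- calls; d$kind <- "dORF"
  tbd <- startCodonDistribution(d)
  expect_false("uORF" %in% tbd$kind)
})

test_that("uORF detection has high power and low FDR over seeds", {
  hits <- 0L; trueN <- 0L; falseCalls <- 0L; totalCalls <- 0L
  for (seed in 1:6) {
    uspec <- data.frame(transcript_id = sprintf("tx%03d", 1:5),
                        start = 12L, length = 60L, start_codon = "ATG")
    s <- simExperiment(seed = seed, nTranscripts = 20,
                       meanRiboDepth = 5000, meanRnaDepth = 100,
                       uorfSpec = uspec)
    fp <- s$libs$ribo[[1]]
    tr <- buildPsiteTracks(fp, estimateOffsets(fp, s$index), s$index)
    calls <- callUtrOrfs(tr, s$index, "UTR5")
    got <- unique(calls$transcript_id)
    hits <- hits + sum(uspec$transcript_id %in% got)
    trueN <- trueN + nrow(uspec)
    falseCalls <- falseCalls + sum(!got %in% uspec$transcript_id)
    totalCalls <- totalCalls + length(got)
  }
  expect_gte(hits / trueN, 0.9)
  expect_lte(falseCalls / max(totalCalls, 1), 0.05)
})
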