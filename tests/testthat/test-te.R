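# helpers to build count matrices with a shared design
teDesign <- function(nRep = 2) {
  data.frame(
    sample_id = c(paste0("ribo_", 1:(2 * nRep)), paste0("rna_", 1:(2 * nRep))),
    modality = rep(c("ribo", "rna"), each = 2 * nRep),
    condition = rep(rep(c("A", "B"), each = nRep), 2))
}

test_that("the abundance and biotype filters behave as printed", {
  seqs <- c(strrep("ACGT", 75), strrep("AGCT", 75), strrep("ATGC", 75))
  anno <- data.frame(transcript_id = c("tx1", "tx2", "tx3"),
                     gene_id = c("g1", "g2", "g3"),
                     biotype = c("protein_coding", "rRNA", "protein_coding"),
                     utr5_len = 30, cds_len = 240, utr3_len = 30)
  idx <- indexFromSeqs(seqs, anno)
  mkTracks <- function(n1, n2, n3, sid) {
    oneTrack <- function(n) c(as.integer(n), rep(0L, 299))
    trackSetOf(list(tx1 = oneTrack(n1), tx2 = oneTrack(n2),
                    tx3 = oneTrack(n3)), sampleId = sid)
  }
  tracks <- list(mkTracks(9, 500, 10, "r1"), mkTracks(9, 500, 10, "r2"))
  rna <- matrix(500L, 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                            c("n1", "n2")))
  cf <- countAndFilter(tracks, rna, idx)
  # 9 ribo reads vs 500 rna -> eliminated for low ribosome coverage
  expect_equal(cf$excluded$reason[cf$excluded$gene_id == "g1"], "low_ribo")
  # rRNA eliminated regardless of counts
  expect_equal(cf$excluded$reason[cf$excluded$gene_id == "g2"],
               "excluded_biotype")
  # exactly 10 reads in both modalities is retained (strict < 10)
  expect_equal(rownames(cf$ribo), "g3")
  expect_error(countAndFilter(tracks, rna, idx, minReads = 1000),
               "all genes filtered")
})

test_that("identical counts across conditions give te_lfc 0", {
  set.seed(21)
  nG <- 30
  base <- matrix(rnbinom(nG * 2, mu = 150, size = 10), nG, 2)
  ribo <- cbind(base, base); rna <- cbind(base, base)
  rownames(ribo) <- rownames(rna) <- sprintf("g%02d", 1:nG)
  colnames(ribo) <- paste0("ribo_", 1:4); colnames(rna) <- paste0("rna_", 1:4)
  res <- classifyTE(differentialTE(ribo, rna, teDesign()))
  expect_equal(res$te_lfc, rep(0, nG), tolerance = 1e-8)
  expect_false(any(res$significant))
})

test_that("an exact ribo doubling with stable normalization gives te_lfc 1", {
  nG <- 40
  base <- matrix(100L, nG, 4)
  ribo <- base; rna <- base
  ribo[1, 3:4] <- 200L                  # gene 1 doubles in condition B
  rownames(ribo) <- rownames(rna) <- sprintf("g%02d", 1:nG)
  colnames(ribo) <- paste0("ribo_", 1:4); colnames(rna) <- paste0("rna_", 1:4)
  res <- differentialTE(ribo, rna, teDesign())
  expect_equal(res$te_lfc[res$gene_id == "g01"], 1, tolerance = 1e-6)
  expect_equal(res$rna_lfc[res$gene_id == "g01"], 0, tolerance = 1e-6)
})

test_that("true TE shifts are recovered with small bias", {
  set.seed(33)
  nG <- 2000; nRep <- 3   # 200 shifted genes on a mostly-null background
  mu <- rlnorm(nG, log(200), 0.5)
  fold <- rep(1, nG); fold[1:200] <- 2^1.5
  ribo <- sapply(1:6, function(j)
    rnbinom(nG, mu = mu * (if (j > 3) fold else 1), size = 10))
  rna <- sapply(1:6, function(j) rnbinom(nG, mu = mu, size = 10))
  rownames(ribo) <- rownames(rna) <- sprintf("g%04d", 1:nG)
  colnames(ribo) <- paste0("ribo_", 1:6); colnames(rna) <- paste0("rna_", 1:6)
  res <- differentialTE(ribo, rna, teDesign(nRep = 3))
  est <- res$te_lfc[match(sprintf("g%04d", 1:200), res$gene_id)]
  expect_lt(abs(mean(est, na.rm = TRUE) - 1.5), 0.1)
})

test_that("swapping condition labels negates te_lfc and keeps p", {
  set.seed(34)
  nG <- 60
  ribo <- matrix(rnbinom(nG * 4, mu = 120, size = 8), nG, 4)
  rna <- matrix(rnbinom(nG * 4, mu = 120, size = 8), nG, 4)
  rownames(ribo) <- rownames(rna) <- sprintf("g%02d", 1:nG)
  colnames(ribo) <- paste0("ribo_", 1:4); colnames(rna) <- paste0("rna_", 1:4)
  d <- teDesign()
  rA <- differentialTE(ribo, rna, d, reference = "A")
  rB <- differentialTE(ribo, rna, d, reference = "B")
  expect_equal(rA$te_lfc, -rB$te_lfc, tolerance = 1e-10)
  expect_equal(rA$p_value, rB$p_value, tolerance = 1e-10)
})

test_that("classification applies the p and log2FC cutoffs jointly", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    rna_lfc = 0, ribo_lfc = 0,
                    te_lfc = c(0.80, 0.50, 2.0),
                    p_value = c(0.001, 0.001, 0.20),
                    q_value = NA_real_)
  cl <- classifyTE(res)
  expect_equal(cl$significant, c(TRUE, FALSE, FALSE))
  expect_equal(cl$direction, c("up", "none", "none"))
  sm <- attr(cl, "summary")
  expect_equal(unname(sm["n_significant"]), 1)
  expect_equal(unname(sm["frac_up"]), 1)
  # a down-shifted significant gene moves the down fraction
  res$te_lfc[2] <- -0.9
  sm2 <- attr(classifyTE(res), "summary")
  expect_equal(unname(sm2["frac_down"]), 0.5)
})

test_that("interaction LFCs agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(99)
  nG <- 150
  mu <- rlnorm(nG, log(150), 0.5)
  fold <- rep(1, nG); fold[1:15] <- 2^1.2
  ribo <- sapply(1:4, function(j)
    rnbinom(nG, mu = mu * (if (j > 2) fold else 1), size = 8))
  rna <- sapply(1:4, function(j) rnbinom(nG, mu = mu, size = 8))
  rownames(ribo) <- rownames(rna) <- sprintf("g%03d", 1:nG)
  colnames(ribo) <- paste0("ribo_", 1:4); colnames(rna) <- paste0("rna_", 1:4)
  d <- teDesign()
  res <- differentialTE(ribo, rna, d)
  cd <- data.frame(modality = factor(d$modality, levels = c("rna", "ribo")),
                   condition = factor(d$condition, levels = c("A", "B")))
  dds <- DESeq2::DESeqDataSetFromMatrix(cbind(ribo, rna), cd,
                                        ~ modality * condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  r2 <- DESeq2::results(dds, name = "modalityribo.conditionB")
  m <- match(res$gene_id, rownames(r2))
  expect_gt(cor(res$te_lfc, r2$log2FoldChange[m]), 0.99)
  expect_lt(mean(abs(res$te_lfc - r2$log2FoldChange[m])), 0.05)
})

test_that("genes with an all-zero modality are excluded with a reason", {
  nG <- 10
  ribo <- matrix(50L, nG, 4); rna <- matrix(50L, nG, 4)
  ribo[3, ] <- 0L
  rownames(ribo) <- rownames(rna) <- sprintf("g%02d", 1:nG)
  colnames(ribo) <- paste0("ribo_", 1:4); colnames(rna) <- paste0("rna_", 1:4)
  res <- differentialTE(ribo, rna, teDesign())
  expect_false("g03" %in% res$gene_id)
  ex <- attr(res, "excluded")
  expect_equal(ex$reason[ex$gene_id == "g03"], "zero_ribo")
})
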