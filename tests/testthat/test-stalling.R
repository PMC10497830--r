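test_that("codon occupancy normalizes site coverage over the 64 codons", {
  idx <- tinyIndex()
  a <- transcriptAnno(idx)
  # tinyIndex CDS codon 3 (0-based) is CCG at positions 24-26
  track <- integer(90); track[25] <- 40L      # P-sites on CCG first nt
  occ <- codonOccupancy(trackSetOf(list(tx1 = track)), idx, "P")
  f <- occupancyFractions(occ)
  expect_equal(unname(f["CCG"]), 1)
  expect_equal(sum(f), 1)

  # uniform coverage recovers the CDS codon composition (brute force)
  trackU <- integer(90); trackU[(a$utr5_len + 1):(a$utr5_len + a$cds_len)] <- 2L
  occU <- codonOccupancy(trackSetOf(list(tx1 = trackU)), idx, "P")
  seqc <- as.character(transcriptSeqs(idx)[["tx1"]])
  cds <- substr(seqc, a$utr5_len + 1, a$utr5_len + a$cds_len)
  codons <- substring(cds, seq(1, 60, 3), seq(3, 60, 3))
  want <- table(codons) / length(codons)
  got <- occupancyFractions(occU)
  expect_equal(unname(got[names(want)]), as.vector(want), tolerance = 1e-12)

  # a P-site at nt 112 credits the A-site codon containing nt 115
  idx2 <- indexFromSeqs(strrep("ACGT", 75),
                        data.frame(transcript_id = "tx1", gene_id = "g1",
                                   biotype = "protein_coding", utr5_len = 30,
                                   cds_len = 240, utr3_len = 30))
  trA <- integer(300); trA[113] <- 7L         # 0-based 112
  occA <- codonOccupancy(trackSetOf(list(tx1 = trA)), idx2, "A")
  seq2 <- strrep("ACGT", 75)
  codonAt115 <- substr(seq2, 30 + ((115 - 30) %/% 3) * 3 + 1,
                       30 + ((115 - 30) %/% 3) * 3 + 3)
  expect_equal(unname(occupancyFractions(occA)[codonAt115]), 1)

  # zero coverage is flagged
  occ0 <- codonOccupancy(trackSetOf(list(tx1 = integer(90))), idx, "P")
  expect_equal(occ0@flag, "no_coverage")
})

test_that("differential codon usage reports ratios and Student's t", {
  o1 <- occupancyOf(codonFractions("CCG", 0.011), "c1")
  o2 <- occupancyOf(codonFractions("CCG", 0.012), "c2")
  o3 <- occupancyOf(codonFractions("CCG", 0.013), "c3")
  n1 <- occupancyOf(codonFractions("CCG", 0.010), "n1")
  n2 <- occupancyOf(codonFractions("CCG", 0.010), "n2")
  n3 <- occupancyOf(codonFractions("CCG", 0.010), "n3")
  d <- differentialCodonUsage(list(o1, o2, o3), list(n1, n2, n3))
  row <- d[d$codon == "CCG", ]
  oracle <- studentTOracle(c(0.011, 0.012, 0.013), c(0.010, 0.010, 0.010))
  expect_equal(row$t_statistic, oracle$t, tolerance = 1e-9)
  expect_equal(row$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(row$mean_ratio, mean(c(1.1, 1.2, 1.3)), tolerance = 1e-9)

  # identical groups: ratios 1, p = 1
  dn <- differentialCodonUsage(list(o1, o2), list(o1, o2))
  expect_equal(dn$mean_ratio, rep(1, 64))
  expect_true(all(dn$p_value > 0.99))

  # doubling CCG in every condition replicate gives mean ratio 2
  dd <- differentialCodonUsage(
    list(occupancyOf(codonFractions("CCG", 0.02)),
         occupancyOf(codonFractions("CCG", 0.02))),
    list(occupancyOf(codonFractions("CCG", 0.01)),
         occupancyOf(codonFractions("CCG", 0.01))))
  expect_equal(dd[dd$codon == "CCG", "mean_ratio"], 2, tolerance = 1e-12)
})

test_that("stall sites exceed the z threshold rule and respect the filters", {
  idx <- indexFromSeqs(strrep("ACGT", 100),
                       data.frame(transcript_id = "tx1", gene_id = "g1",
                                  biotype = "protein_coding", utr5_len = 50,
                                  cds_len = 300, utr3_len = 50))
  # uniform coverage: sigma = 0, degenerate, no sites
  tU <- integer(400); tU[51:350] <- 3L
  sU <- detectStallSites(trackSetOf(list(tx1 = tU)), idx)
  expect_equal(nrow(sU), 0L)
  expect_true(attr(sU, "degenerate"))

  # constructed spike at mu + ~6 sigma gives exactly one site with that z
  set.seed(55)
  base <- rpois(300, 5)
  mu0 <- mean(base); sd0 <- sd(base)
  spike <- as.integer(round(mu0 + 6 * sd0))
  cds <- base; cds[150] <- spike
  tS <- integer(400); tS[51:350] <- cds
  sS <- detectStallSites(trackSetOf(list(tx1 = tS)), idx)
  expect_equal(nrow(sS), 1L)
  expect_equal(sS$position, 149L)
  zExpect <- (spike - mean(cds)) / sd(cds)
  expect_equal(sS$z_score, zExpect, tolerance = 1e-9)

  # a transcript with fewer than 10 reads contributes no sites
  t9 <- integer(400); t9[60] <- 9L
  s9 <- detectStallSites(trackSetOf(list(tx1 = t9)), idx)
  expect_equal(nrow(s9), 0L)

  # raising the threshold never yields more sites
  nAt <- sapply(c(3, 4, 5, 6), function(z)
    nrow(detectStallSites(trackSetOf(list(tx1 = tS)), idx, zThreshold = z)))
  expect_true(all(diff(nAt) <= 0))
})

test_that("per-transcript normalization absorbs expression differences", {
  anno <- data.frame(transcript_id = c("hi", "lo"),
                     gene_id = c("g1", "g2"), biotype = "protein_coding",
                     utr5_len = 50, cds_len = 300, utr3_len = 50)
  idx <- indexFromSeqs(rep(strrep("ACGT", 100), 2), anno)
  set.seed(56)
  hiCds <- rpois(300, 200)            # abundant, no stall
  loCds <- rpois(300, 2); loCds[150] <- 60L   # rare, genuine stall
  mk <- function(cds) { t0 <- integer(400); t0[51:350] <- as.integer(cds); t0 }
  ts <- trackSetOf(list(hi = mk(hiCds), lo = mk(loCds)))
  glob <- detectStallSites(ts, idx)
  # raw merged coverage: the expression gap inflates sigma and hides the
  # rare transcript's genuine stall
  expect_false(any(glob$transcript_id == "lo"))
  norm <- detectStallSites(ts, idx, normalize = "per-transcript")
  expect_true(any(norm$transcript_id == "lo" & norm$codon_index == 49))
  expect_false(any(norm$transcript_id == "hi"))
})

test_that("frameshift calls read the register switch around a stall", {
  a <- data.frame(transcript_id = "tx1", gene_id = "g1",
                  biotype = "protein_coding", utr5_len = 0L, cds_len = 300L,
                  utr3_len = 0L)
  inFrame <- function(idx0) idx0 %% 3 == 0
  # same register on both sides -> none
  tr <- integer(300)
  tr[which(inFrame(0:299))] <- 10L
  expect_equal(detectFrameshift(tr, a, 150L), "none")
  # -1 register downstream: in-frame positions shift to frame 2
  tr2 <- integer(300)
  tr2[which(inFrame(0:299) & 0:299 < 150)] <- 10L
  down <- which((0:299) %% 3 == 2 & 0:299 > 150)
  tr2[down] <- 10L
  expect_equal(detectFrameshift(tr2, a, 150L), "minus1")
  # +1 register downstream
  tr3 <- integer(300)
  tr3[which(inFrame(0:299) & 0:299 < 150)] <- 10L
  tr3[which((0:299) %% 3 == 1 & 0:299 > 150)] <- 10L
  expect_equal(detectFrameshift(tr3, a, 150L), "plus1")
  # site 20 nt from the CDS end with no coverage beyond it: the
  # downstream half has too little signal for a call
  tr4 <- integer(300)
  tr4[which(inFrame(0:299) & 0:299 < 280)] <- 10L
  expect_equal(detectFrameshift(tr4, a, 280L), "insufficient")
})

test_that("simulated frameshifts are recovered at stall sites", {
  s <- simExperiment(seed = 13, nTranscripts = 3, meanRiboDepth = 10000,
    meanRnaDepth = 100,
    stallSpec = data.frame(transcript_id = "tx001", codon_index = 60,
                           fold = 50),
    frameshiftSpec = data.frame(transcript_id = "tx001", position = 181,
                                shift = -1))
  fp <- s$libs$ribo[[1]]
  tr <- buildPsiteTracks(fp, estimateOffsets(fp, s$index), s$index)
  sites <- detectStallSites(tr, s$index)
  sites <- annotateStallSites(sites, tr, s$index)
  hit <- sites[sites$transcript_id == "tx001" & sites$codon_index == 60, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$frameshift, "minus1")
})

test_that("disome pairs are called within 60 nt and not beyond", {
  idx <- indexFromSeqs(strrep("ACGT", 100),
                       data.frame(transcript_id = "tx1", gene_id = "g1",
                                  biotype = "protein_coding", utr5_len = 50,
                                  cds_len = 300, utr3_len = 50))
  a <- transcriptAnno(idx)[1, ]
  mkTrack <- function(positions) {
    t0 <- integer(400); t0[51:350] <- 1L
    t0[51 + positions] <- 60L
    t0
  }
  mu <- 1; sigma <- 4      # representative sample-level moments
  tIso <- mkTrack(150)
  expect_false(detectDisome(tIso, a, 150L, mu, sigma))
  tPair <- mkTrack(c(150, 210))
  expect_true(detectDisome(tPair, a, 150L, mu, sigma))
  expect_true(detectDisome(tPair, a, 210L, mu, sigma))
  t61 <- mkTrack(c(150, 211))
  expect_false(detectDisome(t61, a, 150L, mu, sigma))

  # simulator disome spec: second stall 60 nt upstream, both flagged
  s <- simExperiment(seed = 14, nTranscripts = 3, meanRiboDepth = 10000,
    meanRnaDepth = 100,
    disomeSpec = data.frame(transcript_id = "tx002", codon_index = 50,
                            fold = 40))
  fp <- s$libs$ribo[[1]]
  tr <- buildPsiteTracks(fp, estimateOffsets(fp, s$index), s$index)
  sites <- annotateStallSites(detectStallSites(tr, s$index), tr, s$index)
  pair <- sites[sites$transcript_id == "tx002" &
                  sites$codon_index %in% c(30, 50), ]
  expect_equal(sort(pair$codon_index), c(30, 50))
  expect_true(all(pair$disome))
})

test_that("RNA spikes mark stall artifacts; absent RNA degrades gracefully", {
  idx <- indexFromSeqs(strrep("ACGT", 100),
                       data.frame(transcript_id = "tx1", gene_id = "g1",
                                  biotype = "protein_coding", utr5_len = 50,
                                  cds_len = 300, utr3_len = 50))
  ribo <- integer(400); ribo[51:350] <- 2L; ribo[201] <- 80L
  ts <- trackSetOf(list(tx1 = ribo))
  sites <- detectStallSites(ts, idx)
  expect_equal(nrow(sites), 1L)
  # flat RNA: not an artifact
  rnaFlat <- trackSetOf(list(tx1 = as.integer(rep(c(3L, 4L), 200))),
                        modality = "rna")
  f1 <- flagArtifacts(sites, rnaFlat, idx)
  expect_false(f1$artifact)
  # coincident RNA spike: artifact
  rnaSpike <- psiteTracks(rnaFlat)$tx1
  rnaSpike[202] <- 300L
  f2 <- flagArtifacts(sites, trackSetOf(list(tx1 = rnaSpike),
                                        modality = "rna"), idx)
  expect_true(f2$artifact)
  # no RNA data: warning, flags FALSE
  expect_warning(f3 <- flagArtifacts(sites, NULL, idx), "RNA")
  expect_false(f3$artifact)
})
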