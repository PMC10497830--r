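## Two-condition translatome simulator with known ground truth.
## Counts follow a gamma-Poisson (negative binomial) model with shared
## dispersion; P-sites are placed codon-wise with a tunable in-frame
## probability, an initiation peak at the start codon, programmed stall
## folds, register switches downstream of frameshift positions, disome
## pairs 60 nt apart, and periodic uORF/dORF signal in the UTRs.

#' Build a simulation configuration
#'
#' All defaults describe the study conditions the simulator emulates: two
#' conditions with at least two replicates each, 28-30 nt footprints with a
#' +12 nt P-site offset (plus a 21 nt short-fragment class), strong but
#' imperfect 3-nt periodicity, and negative-binomial count noise.
#'
#' @param seed integer random seed (required; the simulator has no hidden
#'   randomness).
#' @param nTranscripts number of transcripts (one gene per transcript).
#' @param utr5Range,utr3Range integer ranges (nt) for UTR lengths.
#' @param cdsCodonRange integer range for CDS length in codons.
#' @param nReplicates replicates per condition.
#' @param conditionNames two labels, reference first.
#' @param meanRiboDepth,meanRnaDepth mean reads per transcript per library.
#' @param abundanceSdLog log-sd of the lognormal relative transcript
#'   abundances; 0 makes every transcript equally abundant.
#' @param nbDispersion negative-binomial dispersion of per-transcript counts.
#' @param periodicityStrength in-frame P-site probability, in [1/3, 1].
#' @param offsetMap named integer vector: read length -> P-site offset (nt).
#' @param lengthMix named numeric vector: read length -> sampling weight.
#' @param startPeakFold occupancy fold of the initiation codon.
#' @param utrBackgroundRate non-periodic UTR background, as a fraction of
#'   CDS depth.
#' @param uorfRelDensity P-site density of a programmed uORF/dORF, as a
#'   fraction of the host transcript's CDS depth.
#' @param stallSpec,frameshiftSpec,disomeSpec,uorfSpec,dorfSpec programmed
#'   features; see [SimulationConfig-class] for the expected columns.
#' @param teLfcMap named numeric: gene -> true TE log2FC (second condition).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed,
    nTranscripts = 50L,
    utr5Range = c(80L, 160L),
    cdsCodonRange = c(100L, 300L),
    utr3Range = c(80L, 200L),
    nReplicates = 2L,
    conditionNames = c("normal", "senescent"),
    meanRiboDepth = 10000,
    meanRnaDepth = 5000,
    abundanceSdLog = 0.8,
    nbDispersion = 0.1,
    periodicityStrength = 0.9,
    offsetMap = c(`21` = 9L, `28` = 12L, `29` = 12L, `30` = 12L),
    lengthMix = c(`28` = 0.4, `29` = 0.35, `30` = 0.2, `21` = 0.05),
    startPeakFold = 5,
    utrBackgroundRate = 0.01,
    uorfRelDensity = 0.2,
    stallSpec = NULL, frameshiftSpec = NULL, disomeSpec = NULL,
    uorfSpec = NULL, dorfSpec = NULL,
    teLfcMap = numeric(0)) {
  if (missing(seed)) stop("an explicit seed is required")
  emptySpec <- function(x, cols) {
    if (is.null(x)) {
      d <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
      d[] <- lapply(d, function(z) z[0])
      return(d)
    }
    stopifnot(all(cols %in% names(x)))
    x
  }
  new("SimulationConfig",
      nTranscripts = as.integer(nTranscripts),
      utr5Range = as.integer(utr5Range),
      cdsCodonRange = as.integer(cdsCodonRange),
      utr3Range = as.integer(utr3Range),
      nReplicates = as.integer(nReplicates),
      conditionNames = conditionNames,
      meanRiboDepth = meanRiboDepth, meanRnaDepth = meanRnaDepth,
      abundanceSdLog = abundanceSdLog,
      nbDispersion = nbDispersion,
      periodicityStrength = periodicityStrength,
      offsetMap = setNames(as.integer(offsetMap), names(offsetMap)),
      lengthMix = lengthMix / sum(lengthMix),
      startPeakFold = startPeakFold,
      utrBackgroundRate = utrBackgroundRate,
      uorfRelDensity = uorfRelDensity,
      stallSpec = emptySpec(stallSpec,
                            c("transcript_id", "codon_index", "fold")),
      frameshiftSpec = emptySpec(frameshiftSpec,
                                 c("transcript_id", "position", "shift")),
      disomeSpec = emptySpec(disomeSpec,
                             c("transcript_id", "codon_index", "fold")),
      uorfSpec = emptySpec(uorfSpec,
                           c("transcript_id", "start", "length",
                             "start_codon")),
      dorfSpec = emptySpec(dorfSpec,
                           c("transcript_id", "start", "length",
                             "start_codon")),
      teLfcMap = teLfcMap,
      seed = as.integer(seed))
}

.randCodons <- function(n) {
  pool <- setdiff(.codons(), .stopCodons)
  sample(pool, n, replace = TRUE)
}

.randNt <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome with programmed UTR features
#'
#' Builds random transcripts whose CDS starts with ATG, ends with a stop
#' codon and contains no internal in-frame stop. Programmed uORF/dORF start
#' codons are embedded verbatim at their UTR offsets. Deterministic under a
#' fixed seed.
#'
#' @param config A [SimulationConfig-class].
#' @return list with elements `index` ([TranscriptomeIndex-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
simulateTranscriptome <- function(config) {
  set.seed(config@seed)
  n <- config@nTranscripts
  txIds <- sprintf("tx%03d", seq_len(n))
  geneIds <- sprintf("g%03d", seq_len(n))

  u5 <- sample(seq(config@utr5Range[1], config@utr5Range[2]), n, TRUE)
  nCod <- sample(seq(config@cdsCodonRange[1], config@cdsCodonRange[2]), n, TRUE)
  u3 <- sample(seq(config@utr3Range[1], config@utr3Range[2]), n, TRUE)

  # make sure programmed ORFs fit inside the drawn UTRs
  fitUtr <- function(lenVec, spec, rangeMax, what) {
    if (!nrow(spec)) return(lenVec)
    for (i in seq_len(nrow(spec))) {
      j <- match(spec$transcript_id[i], txIds)
      if (is.na(j)) stop("unknown transcript in ", what, " spec: ",
                         spec$transcript_id[i])
      need <- spec$start[i] + spec$length[i]
      if (need > rangeMax)
        stop(what, " does not fit in any admissible UTR: ",
             spec$transcript_id[i], " start=", spec$start[i],
             " length=", spec$length[i])
      lenVec[j] <- max(lenVec[j], as.integer(need + 3L))
    }
    lenVec
  }
  u5 <- fitUtr(u5, config@uorfSpec, config@utr5Range[2] + 60L, "uORF")
  u3 <- fitUtr(u3, config@dorfSpec, config@utr3Range[2] + 60L, "dORF")

  seqs <- character(n)
  for (i in seq_len(n)) {
    utr5 <- .randNt(u5[i])
    cds <- paste0("ATG", paste(.randCodons(nCod[i] - 2L), collapse = ""),
                  sample(.stopCodons, 1L))
    utr3 <- .randNt(u3[i])
    seqs[i] <- paste0(utr5, cds, utr3)
  }

  embed <- function(seqs, spec, offsetFun) {
    if (!nrow(spec)) return(seqs)
    for (k in seq_len(nrow(spec))) {
      i <- match(spec$transcript_id[k], txIds)
      at <- offsetFun(i) + spec$start[k]          # 0-based transcript coord
      codon <- toupper(spec$start_codon[k])
      stopifnot(nchar(codon) == 3L)
      substr(seqs[i], at + 1L, at + 3L) <- codon
    }
    seqs
  }
  seqs <- embed(seqs, config@uorfSpec, function(i) 0L)
  seqs <- embed(seqs, config@dorfSpec, function(i) u5[i] + 3L * nCod[i])

  anno <- data.frame(transcript_id = txIds, gene_id = geneIds,
                     biotype = "protein_coding",
                     utr5_len = as.integer(u5),
                     cds_len = as.integer(3L * nCod),
                     utr3_len = as.integer(u3),
                     utr_cds_overlap = FALSE,
                     stringsAsFactors = FALSE)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- txIds
  index <- new("TranscriptomeIndex", sequences = ss, anno = anno,
               geneMap = setNames(as.list(txIds), geneIds),
               skipped = data.frame(transcript_id = character(),
                                    reason = character(),
                                    stringsAsFactors = FALSE))

  # resolve programmed features, checking bounds
  checkCodon <- function(spec, what) {
    if (!nrow(spec)) return(spec)
    j <- match(spec$transcript_id, txIds)
    if (anyNA(j)) stop("unknown transcript in ", what, " spec")
    if (any(spec$codon_index < 0L | spec$codon_index >= nCod[j]))
      stop(what, " codon_index outside CDS")
    spec
  }
  stalls <- checkCodon(config@stallSpec, "stall")
  disomes <- checkCodon(config@disomeSpec, "disome")
  if (nrow(disomes) && any(disomes$codon_index < 20L))
    stop("disome codon_index must be >= 20 (60 nt of upstream CDS)")
  fs <- config@frameshiftSpec
  if (nrow(fs)) {
    j <- match(fs$transcript_id, txIds)
    if (anyNA(j)) stop("unknown transcript in frameshift spec")
    if (any(fs$position < 0L | fs$position >= 3L * nCod[j]))
      stop("frameshift position outside CDS")
    if (!all(fs$shift %in% c(-1L, 1L))) stop("frameshift shift must be -1/+1")
  }

  teLfc <- setNames(rep(0, n), geneIds)
  if (length(config@teLfcMap)) {
    unknown <- setdiff(names(config@teLfcMap), geneIds)
    if (length(unknown)) stop("unknown gene in teLfcMap: ", unknown[1])
    teLfc[names(config@teLfcMap)] <- config@teLfcMap
  }
  abundance <- setNames(
    stats::rlnorm(n, meanlog = 0, sdlog = config@abundanceSdLog), txIds)

  uorfs <- config@uorfSpec
  if (nrow(uorfs)) uorfs$region <- "UTR5"
  dorfs <- config@dorfSpec
  if (nrow(dorfs)) dorfs$region <- "UTR3"

  truth <- new("GroundTruth", stalls = stalls, frameshifts = fs,
               disomes = disomes, uorfs = uorfs, dorfs = dorfs,
               teLfc = teLfc, abundance = abundance)
  list(index = index, truth = truth)
}

# expected per-nucleotide P-site weights of one transcript (CDS + UTR ORFs
# + background), given the truth; returns a numeric vector over the
# transcript. `lfcScale` multiplies CDS/UTR signal (condition effect).
.psiteWeights <- function(annoRow, truth, config) {
  txLen <- annoRow$utr5_len + annoRow$cds_len + annoRow$utr3_len
  u5 <- annoRow$utr5_len
  nCod <- annoRow$cds_len %/% 3L
  p <- config@periodicityStrength
  frameProb <- c(p, (1 - p) / 2, (1 - p) / 2)

  codW <- rep(1, nCod)
  codW[1] <- codW[1] * config@startPeakFold
  tx <- annoRow$transcript_id
  st <- truth@stalls[truth@stalls$transcript_id == tx, , drop = FALSE]
  if (nrow(st))
    codW[st$codon_index + 1L] <- codW[st$codon_index + 1L] * st$fold
  di <- truth@disomes[truth@disomes$transcript_id == tx, , drop = FALSE]
  if (nrow(di)) {
    codW[di$codon_index + 1L] <- codW[di$codon_index + 1L] * di$fold
    codW[di$codon_index - 20L + 1L] <-
      codW[di$codon_index - 20L + 1L] * di$fold
  }
  # per-nucleotide CDS weights: codon weight x frame probability
  w <- numeric(txLen)
  cdsW <- as.vector(outer(frameProb, codW))   # pos 1..3 within each codon
  cdsIdx <- u5 + seq_len(3L * nCod)
  w[cdsIdx] <- cdsW
  # frameshift: register switch downstream (shift the frame probabilities)
  fs <- truth@frameshifts[truth@frameshifts$transcript_id == tx, , drop = FALSE]
  if (nrow(fs)) {
    for (k in seq_len(nrow(fs))) {
      from <- fs$position[k]      # CDS-relative nt, 0-based
      sh <- fs$shift[k]
      idx <- (from:(3L * nCod - 1L))
      reg <- ((idx %% 3L) - sh) %% 3L + 1L   # which frame prob applies
      codHere <- codW[idx %/% 3L + 1L]
      w[u5 + idx + 1L] <- codHere * frameProb[reg]
    }
  }
  w <- w / sum(w)   # CDS signal normalized; scaled to depth later

  # programmed periodic UTR ORFs
  addOrf <- function(w, spec, regionStart) {
    if (!nrow(spec)) return(w)
    for (k in seq_len(nrow(spec))) {
      a <- regionStart + spec$start[k]
      len <- spec$length[k]
      nC <- len %/% 3L
      ow <- rep(frameProb, nC)
      ow <- ow / sum(ow) * config@uorfRelDensity
      w[a + seq_len(3L * nC)] <- w[a + seq_len(3L * nC)] + ow
    }
    w
  }
  u <- truth@uorfs[truth@uorfs$transcript_id == tx, , drop = FALSE]
  d <- truth@dorfs[truth@dorfs$transcript_id == tx, , drop = FALSE]
  w <- addOrf(w, u, 0L)
  w <- addOrf(w, d, u5 + 3L * nCod)

  # flat UTR background
  utrIdx <- c(seq_len(u5), u5 + 3L * nCod + seq_len(annoRow$utr3_len))
  if (length(utrIdx))
    w[utrIdx] <- w[utrIdx] + config@utrBackgroundRate / length(utrIdx)
  w
}

#' Simulate ribosome-footprint and RNA-seq libraries
#'
#' Draws per-transcript library counts from a negative binomial (the second
#' condition's ribosome means are scaled by `2^teLfc`; RNA is unchanged),
#' places P-sites according to codon weights, periodicity strength,
#' programmed stalls/frameshifts/disomes and UTR ORFs, and converts each
#' P-site to a footprint whose 5' end is `P-site - offsetMap[length]`.
#' RNA fragments (length 50) are placed uniformly.
#'
#' @param index from [simulateTranscriptome()].
#' @param truth from [simulateTranscriptome()].
#' @param config the same [SimulationConfig-class].
#' @return list with `ribo` (list of [FootprintSet-class]), `rna` (list of
#'   [FootprintSet-class]), `rnaCounts` (gene x sample matrix), and
#'   `design` (data.frame sample_id/condition/replicate).
#' @export
simulateLibraries <- function(index, truth, config) {
  set.seed(config@seed + 1L)
  anno <- index@anno
  n <- nrow(anno)
  conds <- config@conditionNames
  lens <- as.integer(names(config@lengthMix))
  offs <- config@offsetMap[names(config@lengthMix)]
  abund <- truth@abundance[anno$transcript_id]
  teFold <- 2^truth@teLfc[anno$gene_id]

  weights <- lapply(seq_len(n), function(i)
    .psiteWeights(anno[i, ], truth, config))
  txLen <- anno$utr5_len + anno$cds_len + anno$utr3_len
  # sequencing yield scales with molar abundance x target length
  riboW <- abund * anno$cds_len
  rnaW <- abund * txLen

  ribo <- list(); rna <- list()
  rnaCountCols <- list(); design <- NULL
  for (ci in c(1L, 2L)) {
    riboMu <- config@meanRiboDepth * n * (riboW / sum(riboW)) *
      (if (ci == 2L) teFold else 1)
    rnaMu <- config@meanRnaDepth * n * (rnaW / sum(rnaW))
    for (r in seq_len(config@nReplicates)) {
      sid <- sprintf("%s_ribo_%d", conds[ci], r)
      if (config@meanRiboDepth <= 0) {
        warning("zero ribosome depth: empty library ", sid)
        nReads <- integer(n)
      } else {
        nReads <- stats::rnbinom(n, mu = riboMu,
                                 size = 1 / config@nbDispersion)
      }
      recs <- vector("list", n)
      for (i in seq_len(n)) {
        if (nReads[i] == 0L) next
        psite <- sample.int(txLen[i], nReads[i], replace = TRUE,
                            prob = weights[[i]]) - 1L
        L <- sample(lens, nReads[i], replace = TRUE,
                    prob = config@lengthMix)
        start <- psite - offs[as.character(L)]
        ok <- start >= 0L & start + L <= txLen[i]
        if (!any(ok)) next
        recs[[i]] <- data.frame(transcript_id = anno$transcript_id[i],
                                start = as.integer(start[ok]),
                                length = as.integer(L[ok]),
                                stringsAsFactors = FALSE)
      }
      recs <- recs[!vapply(recs, is.null, logical(1))]
      rec <- if (length(recs))
        do.call(rbind, c(recs, list(make.row.names = FALSE)))
      else .emptyFootprintRecords()
      ribo[[sid]] <- new("FootprintSet", sampleId = sid,
                         condition = conds[ci], modality = "ribo",
                         records = rec, nDropped = 0L)

      # matched RNA library
      rsid <- sprintf("%s_rna_%d", conds[ci], r)
      if (config@meanRnaDepth <= 0) {
        warning("zero RNA depth: empty library ", rsid)
        rCounts <- integer(n)
      } else {
        rCounts <- stats::rnbinom(n, mu = rnaMu,
                                  size = 1 / config@nbDispersion)
      }
      rrecs <- vector("list", n)
      for (i in seq_len(n)) {
        if (rCounts[i] == 0L) next
        fl <- min(50L, txLen[i])
        start <- sample.int(txLen[i] - fl + 1L, rCounts[i],
                            replace = TRUE) - 1L
        rrecs[[i]] <- data.frame(transcript_id = anno$transcript_id[i],
                                 start = as.integer(start),
                                 length = fl, stringsAsFactors = FALSE)
      }
      rrecs <- rrecs[!vapply(rrecs, is.null, logical(1))]
      rrec <- if (length(rrecs))
        do.call(rbind, c(rrecs, list(make.row.names = FALSE)))
      else .emptyFootprintRecords()
      rna[[rsid]] <- new("FootprintSet", sampleId = rsid,
                         condition = conds[ci], modality = "rna",
                         records = rrec, nDropped = 0L)
      rnaCountCols[[rsid]] <- rCounts
      design <- rbind(design,
                      data.frame(sample_id = c(sid, rsid),
                                 modality = c("ribo", "rna"),
                                 condition = conds[ci], replicate = r,
                                 stringsAsFactors = FALSE))
    }
  }
  rnaCounts <- do.call(cbind, rnaCountCols)
  rownames(rnaCounts) <- anno$gene_id
  storage.mode(rnaCounts) <- "integer"
  list(ribo = ribo, rna = rna, rnaCounts = rnaCounts, design = design)
}

#' Write ground truth to a TSV (lossless long format)
#'
#' @param truth A [GroundTruth-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTruth <- function(truth, path) {
  rows <- list()
  add <- function(feature, df, cols) {
    if (!nrow(df)) return()
    for (i in seq_len(nrow(df))) {
      r <- data.frame(feature = feature, transcript_id = NA_character_,
                      gene_id = NA_character_, position = NA_integer_,
                      length = NA_integer_, codon_index = NA_integer_,
                      fold = NA_real_, shift = NA_integer_,
                      start_codon = NA_character_, te_lfc = NA_real_,
                      value = NA_real_, stringsAsFactors = FALSE)
      for (cl in names(cols)) r[[cl]] <- df[[cols[[cl]]]][i]
      rows[[length(rows) + 1L]] <<- r
    }
  }
  add("stall", truth@stalls,
      list(transcript_id = "transcript_id", codon_index = "codon_index",
           fold = "fold"))
  add("frameshift", truth@frameshifts,
      list(transcript_id = "transcript_id", position = "position",
           shift = "shift"))
  add("disome", truth@disomes,
      list(transcript_id = "transcript_id", codon_index = "codon_index",
           fold = "fold"))
  add("uorf", truth@uorfs,
      list(transcript_id = "transcript_id", position = "start",
           length = "length", start_codon = "start_codon"))
  add("dorf", truth@dorfs,
      list(transcript_id = "transcript_id", position = "start",
           length = "length", start_codon = "start_codon"))
  if (length(truth@teLfc))
    add("te_lfc", data.frame(gene_id = names(truth@teLfc),
                             te_lfc = unname(truth@teLfc),
                             stringsAsFactors = FALSE),
        list(gene_id = "gene_id", te_lfc = "te_lfc"))
  if (length(truth@abundance))
    add("abundance", data.frame(transcript_id = names(truth@abundance),
                                value = unname(truth@abundance),
                                stringsAsFactors = FALSE),
        list(transcript_id = "transcript_id", value = "value"))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), transcript_id = character(),
               gene_id = character(), position = integer(),
               length = integer(), codon_index = integer(), fold = numeric(),
               shift = integer(), start_codon = character(),
               te_lfc = numeric(), value = numeric(),
               stringsAsFactors = FALSE)
  .writeTSV(df, path)
  invisible(path)
}

#' Read ground truth written by [writeTruth()]
#'
#' @param path path to the truth TSV.
#' @return A [GroundTruth-class].
#' @export
readTruth <- function(path) {
  d <- .readTSV(path, colClasses = c(feature = "character",
                                     transcript_id = "character",
                                     gene_id = "character",
                                     start_codon = "character"))
  pick <- function(feature, cols) {
    x <- d[d$feature == feature, cols, drop = FALSE]
    rownames(x) <- NULL
    x
  }
  st <- pick("stall", c("transcript_id", "codon_index", "fold"))
  fs <- pick("frameshift", c("transcript_id", "position", "shift"))
  di <- pick("disome", c("transcript_id", "codon_index", "fold"))
  uo <- pick("uorf", c("transcript_id", "position", "length", "start_codon"))
  names(uo)[2] <- "start"
  if (nrow(uo)) uo$region <- "UTR5"
  do <- pick("dorf", c("transcript_id", "position", "length", "start_codon"))
  names(do)[2] <- "start"
  if (nrow(do)) do$region <- "UTR3"
  te <- d[d$feature == "te_lfc", ]
  ab <- d[d$feature == "abundance", ]
  new("GroundTruth", stalls = st, frameshifts = fs, disomes = di,
      uorfs = uo, dorfs = do,
      teLfc = setNames(te$te_lfc, te$gene_id),
      abundance = setNames(ab$value, ab$transcript_id))
}
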