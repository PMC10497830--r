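## End-to-end convenience wrapper: offsets -> P-site tracks -> TE ->
## stall sites -> uORF/dORF calls -> subset comparisons.

#' Run the full translatome analysis on a two-condition experiment
#'
#' Estimates P-site offsets per ribosome library, builds P-site tracks,
#' computes differential translation efficiency against the RNA counts,
#' detects stall sites (with frameshift/disome/artifact annotation) and
#' calls uORFs/dORFs per library, and compares the TE log2FC distribution
#' of feature-carrying genes against the background. Feature gene sets are
#' the union over libraries.
#'
#' @param index A [TranscriptomeIndex-class].
#' @param riboFps list of ribosome [FootprintSet-class] (both conditions).
#' @param rnaCounts gene x sample count matrix.
#' @param design data.frame `sample_id`, `modality`, `condition`,
#'   `replicate` covering ribo and rna samples.
#' @param rnaFps optional list of RNA [FootprintSet-class] for artifact
#'   flagging.
#' @param zThreshold stall z threshold.
#' @param alpha ORF-calling significance level.
#' @param pCut,lfcCut TE significance cutoffs.
#' @param minReads abundance filter.
#' @return list: `offsets`, `tracks`, `te` (classified), `stalls`
#'   (per-sample list), `uorfs`, `dorfs` (merged call tables with a
#'   `sample_id` column), `stalledGenes`, `uorfGenes`, `dorfGenes`
#'   (character vectors), `comparisons` (list of
#'   [teCdfComparison()] results per feature class).
#' @export
analyzeTranslatome <- function(index, riboFps, rnaCounts, design,
                               rnaFps = NULL, zThreshold = 4, alpha = 0.05,
                               pCut = 0.05, lfcCut = 0.65, minReads = 10) {
  offsets <- lapply(riboFps, estimateOffsets, index = index)
  tracks <- mapply(buildPsiteTracks, riboFps, offsets,
                   MoreArgs = list(index = index), SIMPLIFY = FALSE)
  rnaTracks <- if (!is.null(rnaFps))
    lapply(rnaFps, function(fp)
      buildPsiteTracks(fp, defaultOffsets(unique(fp@records$length)),
                       index)) else NULL

  cf <- countAndFilter(tracks, rnaCounts, index, minReads = minReads)
  te <- classifyTE(differentialTE(cf$ribo, cf$rna, design), pCut = pCut,
                   lfcCut = lfcCut)

  geneOf <- setNames(index@anno$gene_id, index@anno$transcript_id)
  stalls <- list(); uorfs <- list(); dorfs <- list()
  for (s in names(tracks)) {
    st <- detectStallSites(tracks[[s]], index, zThreshold = zThreshold,
                           minReads = minReads)
    rnaTs <- if (!is.null(rnaTracks)) {
      m <- which(vapply(rnaTracks, conditionOf, "") ==
                   tracks[[s]]@condition)
      if (length(m)) rnaTracks[[m[1]]] else NULL
    } else NULL
    st <- annotateStallSites(st, tracks[[s]], index, rnaTs)
    stalls[[s]] <- st
    for (region in c("UTR5", "UTR3")) {
      calls <- callUtrOrfs(tracks[[s]], index, region = region,
                           alpha = alpha)
      calls <- inferStartCodon(calls, index)
      calls <- filterOrfCalls(calls)$retained
      if (nrow(calls)) {
        calls$sample_id <- s
        calls$condition <- tracks[[s]]@condition
      }
      if (region == "UTR5") uorfs[[s]] <- calls else dorfs[[s]] <- calls
    }
  }
  bindCalls <- function(lst) {
    lst <- lst[vapply(lst, nrow, 0L) > 0]
    if (!length(lst)) return(.emptyOrfCalls())
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  uorfTab <- bindCalls(uorfs)
  dorfTab <- bindCalls(dorfs)
  stallTab <- do.call(rbind, c(lapply(names(stalls), function(s) {
    x <- stalls[[s]]
    x$sample_id <- rep(s, nrow(x))
    x
  }), list(make.row.names = FALSE)))

  # a gene carries a feature when it is detected in at least half of the
  # ribosome libraries (robust to single-library noise)
  nLib <- length(tracks)
  majorityGenes <- function(txBySample) {
    perSample <- lapply(txBySample, function(txs)
      unique(geneOf[txs[!is.na(txs)]]))
    tb <- table(unlist(perSample))
    names(tb)[tb >= ceiling(nLib / 2)]
  }
  cleanStalls <- stallTab[!stallTab$artifact, , drop = FALSE]
  bySample <- function(tab) if (nrow(tab))
    majorityGenes(split(tab$transcript_id, tab$sample_id)) else character(0)
  stalledGenes <- bySample(cleanStalls)
  uorfGenes <- bySample(uorfTab)
  dorfGenes <- bySample(dorfTab)

  comparisons <- list()
  for (nm in c("stalled", "uorf", "dorf")) {
    genes <- switch(nm, stalled = stalledGenes, uorf = uorfGenes,
                    dorf = dorfGenes)
    genes <- genes[!is.na(genes)]
    if (length(genes) && length(setdiff(te$gene_id, genes)))
      comparisons[[nm]] <- teCdfComparison(te, genes, subsetName = nm)
  }
  list(offsets = offsets, tracks = tracks, te = te, stalls = stalls,
       stallTable = stallTab, uorfs = uorfTab, dorfs = dorfTab,
       stalledGenes = unname(stalledGenes), uorfGenes = unname(uorfGenes),
       dorfGenes = unname(dorfGenes), comparisons = comparisons,
       excluded = cf$excluded)
}
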