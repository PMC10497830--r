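## Read-length diagnostics, metagene P-site offset estimation, P-site track
## construction, frame profiles and E/P/A site geometry.

#' Read-length histogram of a footprint set
#'
#' @param fp A [FootprintSet-class].
#' @return data.frame with columns `read_length`, `count` (counts sum to
#'   the number of records).
#' @export
readLengthHistogram <- function(fp) {
  r <- fp@records
  if (!nrow(r))
    return(data.frame(read_length = integer(), count = integer()))
  tb <- table(r$length)
  data.frame(read_length = as.integer(names(tb)),
             count = as.integer(tb))
}

#' An offset table filled with the canonical +12 nt offset
#'
#' @param lengths integer read lengths.
#' @return An [OffsetTable-class] with every offset 12 and flag "default".
#' @export
defaultOffsets <- function(lengths = c(21L, 28L, 29L, 30L)) {
  new("OffsetTable",
      offsets = setNames(rep(12L, length(lengths)), as.character(lengths)),
      flags = setNames(rep("default", length(lengths)),
                       as.character(lengths)))
}

#' Estimate P-site offsets from a start-codon metagene
#'
#' For each read length, builds a metagene of footprint 5'-end positions
#' relative to annotated CDS starts over the window \[-40, +20\] nt. The
#' initiation peak sits upstream of the start codon at a distance equal to
#' the P-site offset; the offset is the argmax of that peak (search
#' restricted to \[-18, -6\] for 26-32 nt fragments, to the full upstream
#' window otherwise). A length whose peak does not carry at least
#' `peakFold` times the mean window signal, or with fewer than
#' `minReadsForOffset` reads in the window, falls back to the canonical 12
#' with flag `"default"`/`"insufficient"`. Ties are broken toward the
#' smaller offset (flag `"tie"`).
#'
#' @param fp A ribosome [FootprintSet-class].
#' @param index A [TranscriptomeIndex-class].
#' @param lengths read lengths to estimate.
#' @param window metagene window around the CDS start (nt, inclusive).
#' @param minReadsForOffset minimum in-window reads per length.
#' @param peakFold quality rule: peak vs mean window signal.
#' @return An [OffsetTable-class].
#' @export
estimateOffsets <- function(fp, index, lengths = c(21L, 28L, 29L, 30L),
                            window = c(-40L, 20L),
                            minReadsForOffset = 100L, peakFold = 2) {
  r <- fp@records
  anno <- index@anno
  cdsStart <- setNames(anno$utr5_len, anno$transcript_id)
  rel <- r$start - cdsStart[r$transcript_id]
  inWin <- !is.na(rel) & rel >= window[1] & rel <= window[2]
  offs <- integer(0); flags <- character(0)
  for (L in lengths) {
    sel <- inWin & r$length == L
    key <- as.character(L)
    if (sum(sel) < minReadsForOffset) {
      offs[key] <- 12L; flags[key] <- "insufficient"; next
    }
    d <- rel[sel]
    h <- table(factor(d, levels = window[1]:window[2]))
    searchD <- if (L >= 26L && L <= 32L) (-18L):(-6L) else window[1]:0L
    hs <- h[as.character(searchD)]
    pk <- max(hs)
    if (pk < peakFold * mean(h)) {
      offs[key] <- 12L; flags[key] <- "default"; next
    }
    peaks <- searchD[hs == pk]
    cand <- -peaks                       # offsets; peak at -12 -> offset 12
    offs[key] <- min(cand)
    flags[key] <- if (length(cand) > 1L) "tie" else "ok"
  }
  new("OffsetTable", offsets = offs, flags = flags)
}

#' Build per-transcript P-site tracks
#'
#' Each footprint contributes one count at `start + offset(length)`. Read
#' lengths missing from the offset table use the canonical 12 nt. Reads
#' whose P-site falls outside the transcript are dropped and counted.
#'
#' @param fp A [FootprintSet-class].
#' @param offsetTable An [OffsetTable-class].
#' @param index A [TranscriptomeIndex-class].
#' @return A [PsiteTrackSet-class] covering every transcript in `index`.
#' @export
buildPsiteTracks <- function(fp, offsetTable, index) {
  r <- fp@records
  anno <- index@anno
  txLen <- setNames(Biostrings::width(index@sequences),
                    names(index@sequences))
  off <- offsetTable@offsets[as.character(r$length)]
  off[is.na(off)] <- 12L
  p <- r$start + off
  known <- r$transcript_id %in% anno$transcript_id
  ok <- known & p >= 0L & p < txLen[r$transcript_id]
  tracks <- lapply(setNames(nm = anno$transcript_id),
                   function(tx) integer(txLen[tx]))
  if (any(ok)) {
    byTx <- split(p[ok], r$transcript_id[ok])
    for (tx in names(byTx)) {
      t0 <- tabulate(byTx[[tx]] + 1L, nbins = txLen[tx])
      tracks[[tx]] <- as.integer(t0)
    }
  }
  new("PsiteTrackSet", sampleId = fp@sampleId, condition = fp@condition,
      modality = fp@modality, tracks = tracks,
      nDropped = fp@nDropped + sum(!ok))
}

#' Frame profile of a transcript region
#'
#' Counts P-sites in the three codon frames of a region (frame f collects
#' positions i with `(i - region_start) %% 3 == f`). The dominant frame is
#' the argmax; ties break toward the lowest frame index.
#'
#' @param track integer P-site count vector for one transcript (or a
#'   [PsiteTrackSet-class] plus `transcript`).
#' @param annoRow one-row annotation data.frame for the transcript.
#' @param region `"CDS"`, `"UTR5"` or `"UTR3"`.
#' @return data.frame with `region`, `frame0`, `frame1`, `frame2`,
#'   `dominant_frame`, `total`.
#' @export
frameProfile <- function(track, annoRow, region = "CDS") {
  b <- .regionBounds(annoRow, region)
  if (b[2] <= b[1]) {
    return(data.frame(region = region, frame0 = 0L, frame1 = 0L,
                      frame2 = 0L, dominant_frame = 0L, total = 0L))
  }
  idx <- (b[1] + 1L):b[2]
  fr <- (idx - 1L - b[1]) %% 3L
  cnt <- vapply(0:2, function(f) sum(track[idx][fr == f]), numeric(1))
  data.frame(region = region, frame0 = cnt[1], frame1 = cnt[2],
             frame2 = cnt[3], dominant_frame = .dominantFrame(cnt),
             total = sum(cnt))
}

#' E/P/A-site positions for a P-site coordinate
#'
#' The E site sits 3 nt upstream and the A site 3 nt downstream of the
#' P-site. When an annotation row is supplied, positions falling outside
#' the CDS are flagged invalid.
#'
#' @param psitePos 0-based transcript coordinate of the P-site first
#'   nucleotide.
#' @param annoRow optional one-row annotation data.frame.
#' @return data.frame with columns `site` (E/P/A), `pos`, `valid`.
#' @export
epaPositions <- function(psitePos, annoRow = NULL) {
  pos <- c(E = psitePos - 3L, P = psitePos, A = psitePos + 3L)
  valid <- rep(TRUE, 3L)
  if (!is.null(annoRow)) {
    b <- .cdsBounds(annoRow)
    valid <- pos >= b["start"] & pos < b["end"]
  }
  data.frame(site = c("E", "P", "A"), pos = as.integer(pos),
             valid = unname(valid), row.names = NULL)
}
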