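## uORF/dORF discovery: multitaper periodicity scanning of UTR P-site
## coverage, start-codon inference within a 60-nt window, and the
## >20-nt proximity filter for uORFs.

.emptyOrfCalls <- function() {
  data.frame(transcript_id = character(), kind = character(),
             region = character(), start = integer(), end = integer(),
             frame = integer(), start_codon = character(),
             start_is_ATG = logical(), periodicity_p = numeric(),
             distance_to_cds = integer(), stringsAsFactors = FALSE)
}

#' Call uORFs/dORFs from UTR P-site coverage
#'
#' Scans each transcript's 5'UTR (uORFs) or 3'UTR (dORFs) with overlapping
#' windows (default 60 nt, 15 nt step), tests each window for 3-nt
#' periodicity with [multitaperTest()], merges contiguous significant
#' windows into one region per call, and records the region's dominant
#' frame, its periodicity p-value and its distance to the canonical CDS.
#' Windows with fewer than `minSignal` P-sites or fewer than `minCovered`
#' covered positions are not testable (a handful of reads cannot evidence
#' translation). `alpha` is applied as a Benjamini-Hochberg FDR level
#' across all testable windows of the scan, and a merged region must show
#' frame coherence (dominant-frame fraction >= `minFrameFrac`) - random
#' background coverage is frame-incoherent, periodic translation is not.
#' Transcripts flagged `utr_cds_overlap` in the annotation (isoforms whose
#' UTR is overlapped by another isoform's CDS) are excluded from scanning.
#'
#' Start codons are not inferred here; see [inferStartCodon()] and
#' [filterOrfCalls()] for the downstream annotation and proximity filter.
#'
#' @param trackSet A [PsiteTrackSet-class].
#' @param index A [TranscriptomeIndex-class].
#' @param region `"UTR5"` (uORFs) or `"UTR3"` (dORFs).
#' @param alpha FDR level for the window scan.
#' @param windowLen,stepLen scanning geometry (nt).
#' @param minRegionLen shortest scannable region (nt).
#' @param minSignal,minCovered testability guards per window.
#' @param minFrameFrac frame-coherence requirement on merged regions.
#' @return data.frame of ORF calls (possibly 0 rows): `transcript_id`,
#'   `kind`, `region`, `start`, `end` (0-based half-open, transcript
#'   coords), `frame` (relative to the UTR start), `start_codon`,
#'   `start_is_ATG`, `periodicity_p`, `distance_to_cds`.
#' @export
callUtrOrfs <- function(trackSet, index, region = c("UTR5", "UTR3"),
                        alpha = 0.05, windowLen = 60L, stepLen = 15L,
                        minRegionLen = 30L, minSignal = 10L,
                        minCovered = 5L, minFrameFrac = 0.5) {
  region <- match.arg(region)
  kind <- if (region == "UTR5") "uORF" else "dORF"
  anno <- index@anno

  # pass 1: test every scannable window of every transcript
  wins <- list()
  for (i in seq_len(nrow(anno))) {
    a <- anno[i, ]
    if (isTRUE(a$utr_cds_overlap)) next
    tx <- a$transcript_id
    track <- trackSet@tracks[[tx]]
    if (is.null(track)) next
    b <- .regionBounds(a, region)
    rs <- b[1]; re <- b[2]
    if (re - rs < minRegionLen) next
    starts <- if (re - rs <= windowLen) rs else {
      st <- seq(rs, re - windowLen, by = stepLen)
      if (st[length(st)] + windowLen < re) st <- c(st, re - windowLen)
      st
    }
    for (ws in starts) {
      we <- min(ws + windowLen, re)
      cov <- track[(ws + 1L):we]
      if (sum(cov) < minSignal || sum(cov > 0) < minCovered) next
      res <- multitaperTest(cov, minLen = min(minRegionLen, we - ws))
      wins[[length(wins) + 1L]] <-
        data.frame(transcript_id = tx, ws = ws, we = we,
                   p = res$pValue, stringsAsFactors = FALSE)
    }
  }
  if (!length(wins)) return(.emptyOrfCalls())
  wins <- do.call(rbind, c(wins, list(make.row.names = FALSE)))
  wins$q <- stats::p.adjust(wins$p, method = "BH")
  wins <- wins[wins$q < alpha, , drop = FALSE]
  if (!nrow(wins)) return(.emptyOrfCalls())

  calls <- list()
  for (tx in unique(wins$transcript_id)) {
    a <- anno[match(tx, anno$transcript_id), ]
    track <- trackSet@tracks[[tx]]
    b <- .regionBounds(a, region)
    rs <- b[1]; re <- b[2]
    wtx <- wins[wins$transcript_id == tx, , drop = FALSE]

    # merge overlapping/contiguous significant windows into regions
    ivs <- cbind(wtx$ws, wtx$we)
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    merged <- list(ivs[1, ])
    if (nrow(ivs) > 1) for (w in 2:nrow(ivs)) {
      last <- merged[[length(merged)]]
      if (ivs[w, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], ivs[w, 2]))
      } else merged[[length(merged) + 1L]] <- ivs[w, ]
    }

    for (m in merged) {
      idx <- (m[1] + 1L):m[2]
      cov <- track[idx]
      pos <- idx - 1L                      # 0-based transcript coords
      fr <- (pos - rs) %% 3L
      cnt <- vapply(0:2, function(f) sum(cov[fr == f]), numeric(1))
      if (sum(cnt) == 0 || max(cnt) / sum(cnt) < minFrameFrac) next
      frame <- .dominantFrame(cnt)
      inFrame <- pos[fr == frame & cov > 0]
      if (!length(inFrame)) next
      ostart <- min(inFrame)
      oend <- min(max(inFrame) + 3L, re)
      p <- if (m[2] - m[1] >= minRegionLen) {
        multitaperTest(track[(m[1] + 1L):m[2]], minLen = minRegionLen)$pValue
      } else min(wtx$p)
      dist <- if (kind == "uORF") a$utr5_len - ostart
              else ostart - (a$utr5_len + a$cds_len)
      calls[[length(calls) + 1L]] <- data.frame(
        transcript_id = tx, kind = kind, region = region,
        start = as.integer(ostart), end = as.integer(oend),
        frame = as.integer(frame), start_codon = NA_character_,
        start_is_ATG = NA, periodicity_p = p,
        distance_to_cds = as.integer(dist), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(.emptyOrfCalls())
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}

#' Infer ORF start codons in a window around the periodicity start
#'
#' Searches an `window`-nt area centred on each call's periodicity start
#' (clipped to the call's UTR). Any ATG in the window, regardless of frame,
#' makes the call ATG-starting; otherwise the near-cognate start codon
#' (CTG, GTG, TTG, ACG, ATT, ATC, ATA, AGG, AAG) in the call's frame
#' nearest the periodicity start is chosen; with no candidate the start is
#' `"unknown"` and the call is retained.
#'
#' @param calls ORF-call data.frame from [callUtrOrfs()].
#' @param index A [TranscriptomeIndex-class].
#' @param window total window size (nt), centred on the call start.
#' @return The calls with `start_codon` and `start_is_ATG` filled.
#' @export
inferStartCodon <- function(calls, index, window = 60L) {
  if (!nrow(calls)) return(calls)
  half <- window %/% 2L
  for (i in seq_len(nrow(calls))) {
    a <- .annoRow(index, calls$transcript_id[i])
    b <- .regionBounds(a, calls$region[i])
    s <- calls$start[i]
    ws <- max(s - half, b[1])
    we <- min(s + half, b[2] - 3L)        # last admissible codon start
    if (we < ws) { calls$start_codon[i] <- "unknown"
                   calls$start_is_ATG[i] <- FALSE; next }
    seqc <- .txSeq(index, calls$transcript_id[i])
    cand <- ws:we
    triplets <- substring(seqc, cand + 1L, cand + 3L)
    atg <- cand[triplets == "ATG"]
    if (length(atg)) {
      calls$start_codon[i] <- "ATG"
      calls$start_is_ATG[i] <- TRUE
      next
    }
    inFrame <- (cand - b[1]) %% 3L == calls$frame[i]
    nc <- cand[inFrame & triplets %in% .nearCognateStarts]
    if (length(nc)) {
      best <- nc[which.min(abs(nc - s))]
      calls$start_codon[i] <- substring(seqc, best + 1L, best + 3L)
      calls$start_is_ATG[i] <- FALSE
    } else {
      calls$start_codon[i] <- "unknown"
      calls$start_is_ATG[i] <- FALSE
    }
  }
  calls
}

#' Apply the uORF proximity filter
#'
#' uORFs must start strictly more than `minDistance` nt upstream of the
#' canonical CDS start so a genuine periodic signal can be distinguished
#' from the main ORF's; dORFs are not distance-filtered.
#'
#' @param calls ORF-call data.frame.
#' @param minDistance strict lower bound (nt) on `distance_to_cds` for
#'   uORFs.
#' @return list with `retained` (calls) and `excluded` (calls plus a
#'   `reason` column).
#' @export
filterOrfCalls <- function(calls, minDistance = 20L) {
  if (!nrow(calls))
    return(list(retained = calls,
                excluded = cbind(calls, reason = character(0))))
  drop <- calls$kind == "uORF" & calls$distance_to_cds <= minDistance
  excluded <- calls[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "too_close_to_cds"
  else excluded$reason <- character(0)
  retained <- calls[!drop, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Start-codon distribution of ORF calls
#'
#' @param calls annotated ORF-call data.frame (optionally with a
#'   `condition` column).
#' @return data.frame `kind` (, `condition`), `start_codon`, `count`,
#'   `fraction`; fractions sum to 1 within each kind (and condition).
#' @export
startCodonDistribution <- function(calls) {
  if (!nrow(calls))
    return(data.frame(kind = character(), start_codon = character(),
                      count = integer(), fraction = numeric()))
  byCond <- "condition" %in% names(calls)
  keys <- if (byCond) list(kind = calls$kind, condition = calls$condition)
          else list(kind = calls$kind)
  tb <- stats::aggregate(list(count = rep(1L, nrow(calls))),
                         c(keys, list(start_codon = calls$start_codon)), sum)
  grp <- do.call(paste, tb[setdiff(names(tb), c("start_codon", "count"))])
  tb$fraction <- tb$count / stats::ave(tb$count, grp, FUN = sum)
  tb[order(tb$kind, -tb$fraction), , drop = FALSE]
}
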