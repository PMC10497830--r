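## Codon-level E/P/A occupancy, differential codon usage, stall-site
## detection at the ~4 SD rule, frameshift detection in a 120-nt window,
## disome checks at +/-60 nt, and RNA-based artifact flagging.

#' Normalized codon occupancy at the E, P or A site
#'
#' For each CDS position carrying P-site coverage, the E/A site lies -3/+3
#' nt away; coverage is credited to the codon containing the site position
#' and positions mapping outside the CDS are excluded. Occupancy per codon
#' is its summed site coverage divided by the total over all 64 codons in
#' the sample.
#'
#' @param trackSet A [PsiteTrackSet-class].
#' @param index A [TranscriptomeIndex-class].
#' @param site `"P"`, `"E"` or `"A"`.
#' @return A [CodonOccupancy-class].
#' @export
codonOccupancy <- function(trackSet, index, site = c("P", "E", "A")) {
  site <- match.arg(site)
  delta <- c(E = -3L, P = 0L, A = 3L)[site]
  codons <- .codons()
  acc <- setNames(numeric(64), codons)
  anno <- index@anno
  for (i in seq_len(nrow(anno))) {
    a <- anno[i, ]
    if (a$cds_len == 0L) next
    track <- trackSet@tracks[[a$transcript_id]]
    if (is.null(track)) next
    b <- .cdsBounds(a)
    pidx <- which(track > 0) - 1L            # P-site positions, 0-based
    spos <- pidx + delta                      # site positions
    ok <- spos >= b["start"] & spos < b["end"] &
      pidx >= b["start"] & pidx < b["end"]
    if (!any(ok)) next
    codIdx <- (spos[ok] - b["start"]) %/% 3L + 1L
    cods <- .cdsCodons(index, a$transcript_id)[codIdx]
    tb <- tapply(track[pidx[ok] + 1L], cods, sum)
    acc[names(tb)] <- acc[names(tb)] + tb
  }
  tot <- sum(acc)
  if (tot == 0)
    return(new("CodonOccupancy", sampleId = trackSet@sampleId, site = site,
               fractions = acc, flag = "no_coverage"))
  new("CodonOccupancy", sampleId = trackSet@sampleId, site = site,
      fractions = acc / tot, flag = "ok")
}

#' Differential codon usage between two replicate groups
#'
#' Pairs replicates by list order and reports the per-replicate occupancy
#' ratio (condition / control) per codon, its mean, and a two-sided
#' Student's t-test comparing the normalized occupancies between the
#' groups. Ratios with a zero control occupancy are undefined and flagged
#' rather than dropped.
#'
#' @param cond,ctrl lists of [CodonOccupancy-class] (>= 2 each, same site).
#' @return data.frame with `codon`, per-replicate `ratio_*` columns,
#'   `mean_ratio`, `t_statistic`, `p_value`, `flag`.
#' @export
differentialCodonUsage <- function(cond, ctrl) {
  stopifnot(length(cond) >= 2L, length(ctrl) >= 2L)
  codons <- .codons()
  condM <- vapply(cond, occupancyFractions, numeric(64))[codons, , drop = FALSE]
  ctrlM <- vapply(ctrl, occupancyFractions, numeric(64))[codons, , drop = FALSE]
  nPair <- min(ncol(condM), ncol(ctrlM))
  ratios <- condM[, seq_len(nPair), drop = FALSE] /
    ctrlM[, seq_len(nPair), drop = FALSE]
  ratios[!is.finite(ratios)] <- NA_real_
  out <- data.frame(codon = codons, stringsAsFactors = FALSE)
  for (j in seq_len(nPair)) out[[paste0("ratio_", j)]] <- ratios[, j]
  out$mean_ratio <- rowMeans(ratios)
  out$t_statistic <- NA_real_
  out$p_value <- NA_real_
  out$flag <- "ok"
  for (i in seq_len(64L)) {
    tt <- .studentT(condM[i, ], ctrlM[i, ])
    out$t_statistic[i] <- tt$t
    out$p_value[i] <- tt$p
    if (tt$flag != "ok") out$flag[i] <- tt$flag
    if (anyNA(ratios[i, ])) out$flag[i] <- "undefined_ratio"
  }
  out
}

#' Detect candidate ribosome stall sites
#'
#' Transcripts with fewer than `minReads` total P-sites are excluded
#' first. The mean and standard deviation are computed over the merged
#' per-nucleotide CDS coverage of all retained transcripts in the sample
#' (zeros included), and any CDS position whose count exceeds
#' `mu + zThreshold * sigma` is reported with its z-score. The first and
#' last `trimCodons` codons are not searched (initiation/termination
#' pausing is not an elongation stall). One site is reported per
#' (transcript, codon): the position with the highest count.
#'
#' With `normalize = "per-transcript"`, each transcript's CDS coverage is
#' divided by its own mean before merging, which makes the threshold
#' insensitive to expression differences between transcripts; the default
#' works on raw merged coverage.
#'
#' @param trackSet A ribosome [PsiteTrackSet-class].
#' @param index A [TranscriptomeIndex-class].
#' @param zThreshold z-score threshold (default 4).
#' @param minReads per-transcript read floor (strict `<` exclusion).
#' @param trimCodons codons masked at each CDS end.
#' @param normalize `"global"` (default) or `"per-transcript"`.
#' @return data.frame `transcript_id`, `position` (CDS-relative nt),
#'   `codon_index`, `frame`, `count`, `z_score`; attributes `"mu"`,
#'   `"sigma"`, `"degenerate"`.
#' @export
detectStallSites <- function(trackSet, index, zThreshold = 4,
                             minReads = 10, trimCodons = 5L,
                             normalize = c("global", "per-transcript")) {
  normalize <- match.arg(normalize)
  anno <- index@anno
  keep <- character(0); cdsCov <- list()
  for (i in seq_len(nrow(anno))) {
    a <- anno[i, ]
    if (a$cds_len == 0L) next
    track <- trackSet@tracks[[a$transcript_id]]
    if (is.null(track) || sum(track) < minReads) next
    b <- .cdsBounds(a)
    keep <- c(keep, a$transcript_id)
    cov <- track[(b["start"] + 1L):b["end"]]
    if (normalize == "per-transcript" && mean(cov) > 0)
      cov <- cov / mean(cov)
    cdsCov[[a$transcript_id]] <- cov
  }
  empty <- data.frame(transcript_id = character(), position = integer(),
                      codon_index = integer(), frame = integer(),
                      count = numeric(), z_score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) {
    attr(empty, "mu") <- NA_real_; attr(empty, "sigma") <- NA_real_
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  merged <- unlist(cdsCov, use.names = FALSE)
  mu <- mean(merged); sigma <- stats::sd(merged)
  attr(empty, "mu") <- mu; attr(empty, "sigma") <- sigma
  attr(empty, "degenerate") <- FALSE
  if (!is.finite(sigma) || sigma == 0) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  rows <- list()
  for (tx in keep) {
    cov <- cdsCov[[tx]]
    nC <- length(cov) %/% 3L
    lo <- trimCodons * 3L
    hi <- (nC - trimCodons) * 3L
    if (hi <= lo) next
    pos <- which(cov > mu + zThreshold * sigma) - 1L
    pos <- pos[pos >= lo & pos < hi]
    if (!length(pos)) next
    ci <- pos %/% 3L
    for (u in unique(ci)) {
      p <- pos[ci == u]
      best <- p[which.max(cov[p + 1L])]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, position = as.integer(best),
        codon_index = as.integer(u), frame = as.integer(best %% 3L),
        count = cov[best + 1L],        # on the analysis (normalized) scale
        z_score = (cov[best + 1L] - mu) / sigma,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "mu") <- mu; attr(out, "sigma") <- sigma
  attr(out, "degenerate") <- FALSE
  out
}

#' Frameshift check around a stall site
#'
#' Examines a 120-nt region centred on the stall: the dominant frame is
#' computed separately on the 60-nt upstream and downstream halves (site
#' position excluded). A -1 frameshift is called when the downstream
#' dominant frame equals the upstream one minus 1 (mod 3) and both
#' dominant-frame fractions reach `minFrac`; +1 is symmetric. Halves with
#' fewer than `minPsites` P-sites give no call.
#'
#' @param track integer P-site counts for the transcript.
#' @param annoRow one-row annotation data.frame.
#' @param position stall position, CDS-relative nt.
#' @param window total window (nt, default 120).
#' @param minPsites minimum P-sites per half.
#' @param minFrac dominant-frame fraction required in both halves.
#' @return one of `"none"`, `"minus1"`, `"plus1"`, `"insufficient"`.
#' @export
detectFrameshift <- function(track, annoRow, position, window = 120L,
                             minPsites = 10L, minFrac = 0.5) {
  b <- .cdsBounds(annoRow)
  cds <- track[(b["start"] + 1L):b["end"]]
  half <- window %/% 2L
  upIdx <- max(0L, position - half):(position - 1L)
  dnIdx <- (position + 1L):min(length(cds) - 1L, position + half)
  upIdx <- upIdx[upIdx >= 0L & upIdx < position]
  dnIdx <- dnIdx[dnIdx > position & dnIdx < length(cds)]
  frameStats <- function(idx) {
    if (!length(idx)) return(NULL)
    cnt <- vapply(0:2, function(f) sum(cds[idx[idx %% 3L == f] + 1L]),
                  numeric(1))
    list(cnt = cnt, dom = .dominantFrame(cnt),
         frac = if (sum(cnt) > 0) max(cnt) / sum(cnt) else 0,
         n = sum(cnt))
  }
  up <- frameStats(upIdx); dn <- frameStats(dnIdx)
  if (is.null(up) || is.null(dn) || up$n < minPsites || dn$n < minPsites)
    return("insufficient")
  if (up$frac >= minFrac && dn$frac >= minFrac && up$dom != dn$dom) {
    if (dn$dom == (up$dom - 1L) %% 3L) return("minus1")
    if (dn$dom == (up$dom + 1L) %% 3L) return("plus1")
  }
  "none"
}

#' Disome (collided ribosome) check around a stall site
#'
#' TRUE when another position whose count exceeds
#' `mu + zThreshold * sigma` lies within `span` nt of the stall (both
#' sides), excluding the +/-2 nt immediately around the site itself.
#' `mu`/`sigma` are the sample-level merged-coverage moments from
#' [detectStallSites()].
#'
#' @param track integer P-site counts for the transcript.
#' @param annoRow one-row annotation data.frame.
#' @param position stall position, CDS-relative nt.
#' @param mu,sigma merged CDS coverage moments of the sample.
#' @param span search span (nt, inclusive).
#' @param zThreshold z-score threshold.
#' @return logical.
#' @export
detectDisome <- function(track, annoRow, position, mu, sigma,
                         span = 60L, zThreshold = 4) {
  b <- .cdsBounds(annoRow)
  cds <- track[(b["start"] + 1L):b["end"]]
  d <- seq_along(cds) - 1L - position
  cand <- abs(d) <= span & abs(d) > 2L
  any(cds[cand] > mu + zThreshold * sigma)
}

#' Flag stall sites coinciding with RNA coverage spikes
#'
#' A stall call is an artifact of over-sequenced fragments when the
#' matched RNA coverage around the site (+/-3 nt) also exceeds the RNA
#' track's own `mu + zThreshold * sigma` (the stall rule mirrored on the
#' RNA data). Artifact sites are retained in the output and excluded from
#' downstream comparative analyses by the caller. With no RNA data, all
#' flags are FALSE with a warning.
#'
#' @param sites data.frame from [detectStallSites()].
#' @param rnaTrackSet matched RNA [PsiteTrackSet-class] (or NULL).
#' @param index A [TranscriptomeIndex-class].
#' @param zThreshold z-score threshold for the RNA spike rule.
#' @return `sites` with an `artifact` logical column.
#' @export
flagArtifacts <- function(sites, rnaTrackSet, index, zThreshold = 4) {
  sites$artifact <- FALSE
  if (!nrow(sites)) return(sites)
  if (is.null(rnaTrackSet)) {
    warning("no RNA data supplied; artifact flags set to FALSE")
    return(sites)
  }
  anno <- index@anno
  cdsCov <- list()
  for (tx in unique(c(sites$transcript_id, names(rnaTrackSet@tracks)))) {
    i <- match(tx, anno$transcript_id)
    if (is.na(i) || anno$cds_len[i] == 0L) next
    tr <- rnaTrackSet@tracks[[tx]]
    if (is.null(tr)) next
    b <- .cdsBounds(anno[i, ])
    cdsCov[[tx]] <- tr[(b["start"] + 1L):b["end"]]
  }
  merged <- unlist(cdsCov, use.names = FALSE)
  if (!length(merged)) {
    warning("RNA tracks empty; artifact flags set to FALSE")
    return(sites)
  }
  mu <- mean(merged); sigma <- stats::sd(merged)
  if (!is.finite(sigma) || sigma == 0) return(sites)
  for (i in seq_len(nrow(sites))) {
    cov <- cdsCov[[sites$transcript_id[i]]]
    if (is.null(cov)) next
    win <- (sites$position[i] - 3L):(sites$position[i] + 3L)
    win <- win[win >= 0L & win < length(cov)]
    sites$artifact[i] <- any(cov[win + 1L] > mu + zThreshold * sigma)
  }
  sites
}

#' Annotate stall sites with frameshift, disome and artifact flags
#'
#' Convenience wrapper running [detectFrameshift()], [detectDisome()] and
#' [flagArtifacts()] over a stall-site table.
#'
#' @param sites data.frame from [detectStallSites()] (with `mu`/`sigma`
#'   attributes).
#' @param trackSet the ribosome [PsiteTrackSet-class] the sites came from.
#' @param index A [TranscriptomeIndex-class].
#' @param rnaTrackSet optional matched RNA [PsiteTrackSet-class].
#' @return `sites` with `frameshift`, `disome`, `artifact` columns.
#' @export
annotateStallSites <- function(sites, trackSet, index, rnaTrackSet = NULL) {
  mu <- attr(sites, "mu"); sigma <- attr(sites, "sigma")
  sites$frameshift <- character(nrow(sites))
  sites$disome <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    a <- .annoRow(index, sites$transcript_id[i])
    track <- trackSet@tracks[[sites$transcript_id[i]]]
    sites$frameshift[i] <- detectFrameshift(track, a, sites$position[i])
    sites$disome[i] <- detectDisome(track, a, sites$position[i], mu, sigma)
  }
  if (!is.null(rnaTrackSet) || nrow(sites) == 0)
    sites <- flagArtifacts(sites, rnaTrackSet, index)
  else sites$artifact <- FALSE
  sites
}
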