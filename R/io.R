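## Readers and writers for the external formats the pipeline touches.
## Conventions shared by every module: coordinates are 0-based half-open in
## transcript space; sequences are DNA (T, not U).

#' Load a transcriptome index from FASTA plus annotation
#'
#' Reads transcript sequences (FASTA) and the 5'UTR/CDS/3'UTR partition of
#' each transcript, either from a TSV with columns `transcript_id`,
#' `utr5_len`, `cds_len`, `utr3_len` (optionally `gene_id`, `biotype`,
#' `utr_cds_overlap`) or from a GTF/GFF file with exon/CDS features, which
#' is collapsed to transcript coordinates at load time. Transcripts that
#' violate the model invariants (region lengths not summing to the sequence
#' length, CDS length not divisible by 3, id missing from the FASTA) are
#' skipped with a warning and recorded in the skipped-list.
#'
#' @param fastaPath path to the transcript FASTA.
#' @param annotationPath path to the annotation TSV or GTF/GFF.
#' @return A [TranscriptomeIndex-class].
#' @export
loadTranscriptome <- function(fastaPath, annotationPath) {
  if (!file.exists(fastaPath)) stop("FASTA not found: ", fastaPath)
  if (!file.exists(annotationPath))
    stop("annotation not found: ", annotationPath)
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  anno <- if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", annotationPath,
                    ignore.case = TRUE)) {
    .gtfToTranscriptAnno(annotationPath)
  } else {
    .readTSV(annotationPath)
  }
  need <- c("transcript_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(anno)))
    stop("annotation must provide columns: ", paste(need, collapse = ", "))
  if (is.null(anno$gene_id)) anno$gene_id <- anno$transcript_id
  if (is.null(anno$biotype)) anno$biotype <- "protein_coding"
  if (is.null(anno$utr_cds_overlap)) anno$utr_cds_overlap <- FALSE

  skipped <- data.frame(transcript_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- logical(nrow(anno))
  sw <- Biostrings::width(seqs)
  for (i in seq_len(nrow(anno))) {
    a <- anno[i, ]
    j <- match(a$transcript_id, names(seqs))
    reason <- if (is.na(j)) "missing_sequence"
      else if (a$utr5_len + a$cds_len + a$utr3_len != sw[j]) "length_mismatch"
      else if (a$cds_len > 0 && a$cds_len %% 3L != 0L) "cds_not_multiple_of_3"
      else if (a$utr5_len < 0 || a$cds_len < 0 || a$utr3_len < 0)
        "negative_region"
      else NA_character_
    if (is.na(reason)) keep[i] <- TRUE
    else skipped <- rbind(skipped,
                          data.frame(transcript_id = a$transcript_id,
                                     reason = reason,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(skipped))
    warning(nrow(skipped), " transcript(s) skipped at load (",
            paste(unique(skipped$reason), collapse = ", "), ")")
  anno <- anno[keep, , drop = FALSE]
  rownames(anno) <- NULL
  anno$utr5_len <- as.integer(anno$utr5_len)
  anno$cds_len <- as.integer(anno$cds_len)
  anno$utr3_len <- as.integer(anno$utr3_len)
  seqs <- seqs[anno$transcript_id]
  gm <- split(anno$transcript_id, anno$gene_id)
  new("TranscriptomeIndex", sequences = seqs, anno = anno,
      geneMap = gm[unique(anno$gene_id)], skipped = skipped)
}

# Collapse GTF/GFF exon/CDS features (read with rtracklayer) to
# transcript-space region lengths. utr5_len is the transcript coordinate of
# the 5'-most CDS base; a stop_codon feature, when present, is counted into
# the CDS.
.gtfToTranscriptAnno <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if (is.null(md$transcript_id))
    stop("GTF/GFF lacks transcript_id attributes")
  g <- data.frame(feature = as.character(md$type),
                  start = md$start, end = md$end,
                  strand = as.character(md$strand),
                  transcript_id = md$transcript_id,
                  gene_id = if (!is.null(md$gene_id)) md$gene_id
                            else md$transcript_id,
                  biotype0 = if (!is.null(md$transcript_biotype))
                               md$transcript_biotype else NA_character_,
                  stringsAsFactors = FALSE)
  g <- g[!is.na(g$transcript_id) &
           g$feature %in% c("exon", "CDS", "stop_codon"), ]
  out <- lapply(split(g, g$transcript_id), function(tx) {
    ex <- tx[tx$feature == "exon", ]
    if (!nrow(ex)) return(NULL)
    minus <- ex$strand[1] == "-"
    ex <- ex[order(ex$start, decreasing = minus), ]
    txLen <- sum(ex$end - ex$start + 1L)
    cds <- tx[tx$feature %in% c("CDS", "stop_codon"), ]
    if (!nrow(cds)) {
      u5 <- 0L; cl <- 0L
    } else {
      cl <- sum(cds$end - cds$start + 1L)
      gpos <- if (minus) max(cds$end) else min(cds$start)
      # transcript coordinate (0-based) of the genomic CDS 5' boundary
      u5 <- 0L
      for (k in seq_len(nrow(ex))) {
        w <- ex$end[k] - ex$start[k] + 1L
        inEx <- gpos >= ex$start[k] && gpos <= ex$end[k]
        if (inEx) {
          u5 <- u5 + if (minus) ex$end[k] - gpos else gpos - ex$start[k]
          break
        }
        u5 <- u5 + w
      }
    }
    data.frame(transcript_id = tx$transcript_id[1],
               gene_id = tx$gene_id[1],
               biotype = ifelse(is.na(tx$biotype0[1]), "protein_coding",
                                tx$biotype0[1]),
               utr5_len = as.integer(u5), cds_len = as.integer(cl),
               utr3_len = as.integer(txLen - u5 - cl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a transcriptome index back to FASTA + annotation TSV
#'
#' @param index A [TranscriptomeIndex-class].
#' @param fastaPath,annotationPath output paths.
#' @return Invisibly, the paths.
#' @export
writeTranscriptome <- function(index, fastaPath, annotationPath) {
  Biostrings::writeXStringSet(index@sequences, fastaPath)
  .writeTSV(index@anno, annotationPath)
  invisible(c(fastaPath, annotationPath))
}

#' Load footprint intervals from a transcript-coordinate BED file
#'
#' The dialect is BED (3+ columns, tab or space separated): transcript id,
#' 0-based start, end (half-open); interval length is the read length.
#' Records on transcripts absent from `index` or extending past a transcript
#' end are dropped and counted; malformed lines are fatal with their line
#' number.
#'
#' @param bedPath path to the BED file.
#' @param index A [TranscriptomeIndex-class].
#' @param sampleId sample identifier.
#' @param modality `"ribo"` or `"rna"`.
#' @param condition optional condition label.
#' @return A [FootprintSet-class].
#' @export
loadFootprints <- function(bedPath, index, sampleId,
                           modality = c("ribo", "rna"), condition = NA) {
  modality <- match.arg(modality)
  if (!file.exists(bedPath)) stop("BED not found: ", bedPath)
  lines <- readLines(bedPath)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(new("FootprintSet", sampleId = sampleId,
               condition = as.character(condition), modality = modality,
               records = .emptyFootprintRecords(), nDropped = 0L))
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  tx <- vapply(fields, `[`, character(1), 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(s) | is.na(e) | e <= s)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-integer or empty interval")
  txLen <- Biostrings::width(index@sequences)[match(tx, names(index@sequences))]
  unknown <- is.na(txLen)
  oob <- !unknown & (s < 0L | e > txLen)
  drop <- unknown | oob
  if (any(unknown))
    warning(sum(unknown), " record(s) on unknown transcripts dropped")
  if (any(oob))
    warning(sum(oob), " out-of-bounds record(s) dropped")
  rec <- data.frame(transcript_id = tx[!drop], start = s[!drop],
                    length = e[!drop] - s[!drop], stringsAsFactors = FALSE)
  new("FootprintSet", sampleId = sampleId,
      condition = as.character(condition), modality = modality,
      records = rec, nDropped = sum(drop))
}

#' Write a footprint set as BED6 on transcript coordinates
#'
#' @param fp A [FootprintSet-class].
#' @param bedPath output path.
#' @return Invisibly, the path.
#' @export
writeFootprints <- function(fp, bedPath) {
  r <- fp@records
  bed <- data.frame(r$transcript_id, r$start, r$start + r$length, ".", 0L, "+")
  utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bedPath)
}

#' Load gene sets from a GMT file
#'
#' GMT: one set per line, tab separated: name, description, gene ids.
#' Duplicate genes within a set are deduplicated; sets empty after parsing
#' are dropped with a warning.
#'
#' @param gmtPath path to the GMT file.
#' @return A [GeneSetCollection-class].
#' @export
loadGeneSets <- function(gmtPath) {
  if (!file.exists(gmtPath)) stop("GMT not found: ", gmtPath)
  lines <- readLines(gmtPath)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  dropped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) { dropped <- dropped + 1L; next }
    sets[[f[1]]] <- genes
  }
  if (dropped) warning(dropped, " empty gene set(s) dropped")
  new("GeneSetCollection", sets = sets)
}

#' Load a gene-gene network from a two-column edge list TSV
#'
#' Reversed duplicates are collapsed to one undirected edge; self-loops are
#' dropped.
#'
#' @param tsvPath path to the edge list (two gene columns, no header).
#' @return A [NetworkGraph-class].
#' @export
loadNetwork <- function(tsvPath) {
  if (!file.exists(tsvPath)) stop("network file not found: ", tsvPath)
  e <- utils::read.table(tsvPath, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(e) < 2L) stop("network TSV needs two gene columns")
  networkFromEdges(e[[1]], e[[2]])
}

#' Build a network from edge endpoint vectors
#'
#' @param from,to character vectors of gene ids (parallel).
#' @return A [NetworkGraph-class] with canonical, deduplicated edges.
#' @export
networkFromEdges <- function(from, to) {
  a <- pmin(as.character(from), as.character(to))
  b <- pmax(as.character(from), as.character(to))
  keep <- a != b
  e <- unique(data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE))
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  new("NetworkGraph", edges = e)
}

#' Load a gene count table (genes x samples TSV)
#'
#' First column is the gene id; remaining columns are samples.
#'
#' @param path path to the TSV.
#' @return integer matrix with gene rownames.
#' @export
loadCounts <- function(path) {
  d <- .readTSV(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a gene count matrix as TSV
#'
#' @param counts matrix with gene rownames.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  .writeTSV(df, path)
  invisible(path)
}
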