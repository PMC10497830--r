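## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for riboPatterns containers
#' @param x An object.
#' @param ... Unused.
#' @description Small accessor layer so user code never reaches into slots.
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x, ...) standardGeneric("transcriptIds"))

#' @rdname accessors
#' @export
setMethod("transcriptIds", "TranscriptomeIndex",
          function(x, ...) x@anno$transcript_id)

#' @rdname accessors
#' @export
setGeneric("transcriptAnno", function(x, ...) standardGeneric("transcriptAnno"))

#' @rdname accessors
#' @export
setMethod("transcriptAnno", "TranscriptomeIndex", function(x, ...) x@anno)

#' @rdname accessors
#' @export
setGeneric("transcriptSeqs", function(x, ...) standardGeneric("transcriptSeqs"))

#' @rdname accessors
#' @export
setMethod("transcriptSeqs", "TranscriptomeIndex", function(x, ...) x@sequences)

#' @rdname accessors
#' @export
setGeneric("geneMap", function(x, ...) standardGeneric("geneMap"))

#' @rdname accessors
#' @export
setMethod("geneMap", "TranscriptomeIndex", function(x, ...) x@geneMap)

#' @rdname accessors
#' @export
setGeneric("skippedTranscripts",
           function(x, ...) standardGeneric("skippedTranscripts"))

#' @rdname accessors
#' @export
setMethod("skippedTranscripts", "TranscriptomeIndex",
          function(x, ...) x@skipped)

#' @rdname accessors
#' @export
setGeneric("footprintRecords",
           function(x, ...) standardGeneric("footprintRecords"))

#' @rdname accessors
#' @export
setMethod("footprintRecords", "FootprintSet", function(x, ...) x@records)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x, ...) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setMethod("sampleId", "FootprintSet", function(x, ...) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "PsiteTrackSet", function(x, ...) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("modality", function(x, ...) standardGeneric("modality"))

#' @rdname accessors
#' @export
setMethod("modality", "FootprintSet", function(x, ...) x@modality)

#' @rdname accessors
#' @export
setMethod("modality", "PsiteTrackSet", function(x, ...) x@modality)

#' @rdname accessors
#' @export
setGeneric("conditionOf", function(x, ...) standardGeneric("conditionOf"))

#' @rdname accessors
#' @export
setMethod("conditionOf", "FootprintSet", function(x, ...) x@condition)

#' @rdname accessors
#' @export
setMethod("conditionOf", "PsiteTrackSet", function(x, ...) x@condition)

#' @rdname accessors
#' @export
setGeneric("psiteTracks", function(x, ...) standardGeneric("psiteTracks"))

#' @rdname accessors
#' @export
setMethod("psiteTracks", "PsiteTrackSet", function(x, ...) x@tracks)

#' @rdname accessors
#' @export
setGeneric("nDropped", function(x, ...) standardGeneric("nDropped"))

#' @rdname accessors
#' @export
setMethod("nDropped", "FootprintSet", function(x, ...) x@nDropped)

#' @rdname accessors
#' @export
setMethod("nDropped", "PsiteTrackSet", function(x, ...) x@nDropped)

#' @rdname accessors
#' @export
setGeneric("offsets", function(x, ...) standardGeneric("offsets"))

#' @rdname accessors
#' @export
setMethod("offsets", "OffsetTable", function(x, ...) x@offsets)

#' @rdname accessors
#' @export
setGeneric("offsetFlags", function(x, ...) standardGeneric("offsetFlags"))

#' @rdname accessors
#' @export
setMethod("offsetFlags", "OffsetTable", function(x, ...) x@flags)

#' @rdname accessors
#' @export
setGeneric("occupancyFractions",
           function(x, ...) standardGeneric("occupancyFractions"))

#' @rdname accessors
#' @export
setMethod("occupancyFractions", "CodonOccupancy", function(x, ...) x@fractions)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x, ...) x@sets)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("networkEdges", "NetworkGraph", function(x, ...) x@edges)

#' @rdname accessors
#' @export
setGeneric("totalEdges", function(x, ...) standardGeneric("totalEdges"))

#' @rdname accessors
#' @export
setMethod("totalEdges", "NetworkGraph", function(x, ...) nrow(x@edges))

#' @rdname accessors
#' @export
setGeneric("trueTeLfc", function(x, ...) standardGeneric("trueTeLfc"))

#' @rdname accessors
#' @export
setMethod("trueTeLfc", "GroundTruth", function(x, ...) x@teLfc)

## show methods ------------------------------------------------------------

setMethod("show", "TranscriptomeIndex", function(object) {
  cat("TranscriptomeIndex with", nrow(object@anno), "transcripts,",
      length(object@geneMap), "genes\n")
  if (nrow(object@skipped))
    cat("  ", nrow(object@skipped), "transcripts skipped at load\n")
})

setMethod("show", "FootprintSet", function(object) {
  cat(sprintf("FootprintSet '%s' (%s, condition %s): %d records, %d dropped\n",
              object@sampleId, object@modality,
              ifelse(is.na(object@condition), "<NA>", object@condition),
              nrow(object@records), object@nDropped))
})

setMethod("show", "PsiteTrackSet", function(object) {
  cat(sprintf("PsiteTrackSet '%s' (%s): %d transcripts, %.0f P-sites, %d dropped\n",
              object@sampleId, object@modality, length(object@tracks),
              sum(vapply(object@tracks, sum, numeric(1))), object@nDropped))
})

setMethod("show", "OffsetTable", function(object) {
  cat("OffsetTable:\n")
  print(data.frame(read_length = as.integer(names(object@offsets)),
                   offset = unname(object@offsets),
                   flag = unname(object@flags)), row.names = FALSE)
})

setMethod("show", "CodonOccupancy", function(object) {
  top <- sort(object@fractions, decreasing = TRUE)[1:5]
  cat(sprintf("CodonOccupancy '%s' %s-site [%s]; top codons: %s\n",
              object@sampleId, object@site, object@flag,
              paste(sprintf("%s=%.3f", names(top), top), collapse = " ")))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets;",
      "median size", if (length(object@sets))
        stats::median(lengths(object@sets)) else 0, "\n")
})

setMethod("show", "NetworkGraph", function(object) {
  cat("NetworkGraph with", nrow(object@edges), "edges over",
      length(unique(c(object@edges$a, object@edges$b))), "genes\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d transcripts, %d replicates x {%s},\n",
                     "  ribo depth %g, rna depth %g, dispersion %g, ",
                     "periodicity %.2f, seed %d\n"),
              object@nTranscripts, object@nReplicates,
              paste(object@conditionNames, collapse = ", "),
              object@meanRiboDepth, object@meanRnaDepth,
              object@nbDispersion, object@periodicityStrength, object@seed))
  cat(sprintf("  programmed: %d stalls, %d frameshifts, %d disomes, %d uORFs, %d dORFs, %d TE shifts\n",
              nrow(object@stallSpec), nrow(object@frameshiftSpec),
              nrow(object@disomeSpec), nrow(object@uorfSpec),
              nrow(object@dorfSpec), length(object@teLfcMap)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d stalls, %d frameshifts, %d disomes, %d uORFs, %d dORFs, %d nonzero TE shifts\n",
              nrow(object@stalls), nrow(object@frameshifts),
              nrow(object@disomes), nrow(object@uorfs), nrow(object@dorfs),
              sum(object@teLfc != 0)))
})
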