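#' @include AllClasses.R
NULL

#' Minimum free energy of a fold
#' @param object a \code{FoldResult} or \code{HairpinCandidate}
#' @return numeric MFE in kcal/mol
#' @export
setGeneric("mfe", function(object) standardGeneric("mfe"))

#' @rdname mfe
#' @export
setMethod("mfe", "FoldResult", function(object) object@mfe)

#' @rdname mfe
#' @export
setMethod("mfe", "HairpinCandidate", function(object) object@fold@mfe)

#' Dot-bracket structure string
#' @param object a \code{FoldResult}
#' @export
setGeneric("foldStructure", function(object) standardGeneric("foldStructure"))

#' @rdname foldStructure
#' @export
setMethod("foldStructure", "FoldResult", function(object) object@structure)

#' Base pairs of a fold
#' @param object a \code{FoldResult}
#' @return two-column matrix of 1-based indices (i, j), i < j
#' @export
setGeneric("basePairs", function(object) standardGeneric("basePairs"))

#' @rdname basePairs
#' @export
setMethod("basePairs", "FoldResult", function(object) object@pairs)

#' Accessors for the planted truth
#' @param object a \code{TruthSet}
#' @return a data.frame
#' @export
setGeneric("truthMirnas", function(object) standardGeneric("truthMirnas"))
#' @rdname truthMirnas
#' @export
setMethod("truthMirnas", "TruthSet", function(object) object@mirnas)

#' @rdname truthMirnas
#' @export
setGeneric("truthCleavages", function(object) standardGeneric("truthCleavages"))
#' @rdname truthMirnas
#' @export
setMethod("truthCleavages", "TruthSet", function(object) object@cleavages)

#' @rdname truthMirnas
#' @export
setGeneric("truthDe", function(object) standardGeneric("truthDe"))
#' @rdname truthMirnas
#' @export
setMethod("truthDe", "TruthSet", function(object) object@de)

#' Transcript accessors
#' @param object a \code{TranscriptSet}
#' @export
setGeneric("txSequences", function(object) standardGeneric("txSequences"))
#' @rdname txSequences
#' @export
setMethod("txSequences", "TranscriptSet", function(object) object@sequences)

#' @rdname txSequences
#' @export
setGeneric("txSegments", function(object) standardGeneric("txSegments"))
#' @rdname txSequences
#' @export
setMethod("txSegments", "TranscriptSet", function(object) object@segments)

#' Positions of a degradome profile
#' @param object a \code{DegradomeProfile}
#' @return data.frame with pos, raw, norm
#' @export
setGeneric("profilePositions",
           function(object) standardGeneric("profilePositions"))
#' @rdname profilePositions
#' @export
setMethod("profilePositions", "DegradomeProfile",
          function(object) object@positions)

#' Census accessors
#' @param object a \code{CensusReport}
#' @export
setGeneric("censusTotals", function(object) standardGeneric("censusTotals"))
#' @rdname censusTotals
#' @export
setMethod("censusTotals", "CensusReport", function(object) object@totals)

#' @rdname censusTotals
#' @export
setGeneric("censusClasses", function(object) standardGeneric("censusClasses"))
#' @rdname censusTotals
#' @export
setMethod("censusClasses", "CensusReport",
          function(object) object@classPartition)

#' @rdname censusTotals
#' @export
setGeneric("censusSizes", function(object) standardGeneric("censusSizes"))
#' @rdname censusTotals
#' @export
setMethod("censusSizes", "CensusReport",
          function(object) object@sizeDistribution)

#' @rdname censusTotals
#' @export
setGeneric("censusFirstBase",
           function(object) standardGeneric("censusFirstBase"))
#' @rdname censusTotals
#' @export
setMethod("censusFirstBase", "CensusReport", function(object) object@firstBase)

setMethod("show", "FoldResult", function(object) {
  cat("FoldResult:", nchar(object@structure), "nt,",
      nrow(object@pairs), "pairs, MFE", sprintf("%.1f", object@mfe),
      "kcal/mol\n")
  cat(" ", object@structure, "\n")
})

setMethod("show", "HairpinCandidate", function(object) {
  cat(sprintf("HairpinCandidate %s:%d-%d(%s) [%s]\n", object@chrom,
              object@start, object@end, object@strand, object@status))
  cat(sprintf("  mature %s (%s arm, n=%d)  MFE %.1f\n", object@matureSeq,
              object@arm, object@matureCount, object@fold@mfe))
  if (!is.na(object@starSeq))
    cat(sprintf("  star   %s (n=%d)\n", object@starSeq, object@starCount))
  flags <- names(object@ledger)[object@ledger]
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
})

setMethod("show", "CensusReport", function(object) {
  t <- object@totals
  cat("CensusReport:", t["filtered_reads"], "reads (",
      t["filtered_distinct"], "distinct ) in window;",
      t["mapped_distinct"], "distinct mapped\n")
  print(object@classPartition)
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@mirnas), "planted miRNAs,",
      nrow(object@cleavages), "planted cleavage sites,",
      nrow(object@de), "planted DE probes\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d-chr %d-nt genome, %d planted miRNAs, depth %g, seed %d\n",
    object@nChromosomes, object@genomeLength, object@nMirnas,
    object@readDepth, object@seed))
})

setMethod("show", "DegradomeProfile", function(object) {
  cat(sprintf("DegradomeProfile %s (stage %s): %d occupied positions\n",
              object@transcript, object@stage, nrow(object@positions)))
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet:", length(object@sequences), "transcripts\n")
})
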