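#' Accessors for CloneSight containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a CloneSight object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))
#' @rdname accessors
#' @export
setGeneric("cloneSequences", function(x) standardGeneric("cloneSequences"))
#' @rdname accessors
#' @export
setGeneric("cloneExemplars", function(x) standardGeneric("cloneExemplars"))
#' @rdname accessors
#' @export
setGeneric("cloneCounts", function(x) standardGeneric("cloneCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("diagnosticIndex", function(x) standardGeneric("diagnosticIndex"))
#' @rdname accessors
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))
#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setGeneric("isAnnotated", function(x) standardGeneric("isAnnotated"))
#' @rdname accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))
#' @rdname accessors
#' @export
setGeneric("sampleIndex", function(x) standardGeneric("sampleIndex"))
#' @rdname accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @export
setGeneric("germlineSegments", function(x) standardGeneric("germlineSegments"))
#' @rdname accessors
#' @export
setGeneric("annotationHits", function(x) standardGeneric("annotationHits"))
#' @rdname accessors
#' @export
setGeneric("mrdTable", function(x) standardGeneric("mrdTable"))

#' @rdname accessors
setMethod("nClones", "CloneTable", function(x) length(x@sequences))
#' @rdname accessors
setMethod("cloneSequences", "CloneTable", function(x) x@sequences)
#' @rdname accessors
setMethod("cloneExemplars", "CloneTable", function(x) x@exemplars)
#' @rdname accessors
setMethod("cloneCounts", "CloneTable", function(x) {
  m <- x@counts
  dimnames(m) <- list(x@sequences, x@sampleLabels)
  m
})
#' @rdname accessors
setMethod("sampleLabels", "CloneTable", function(x) x@sampleLabels)
#' @rdname accessors
setMethod("diagnosticIndex", "CloneTable", function(x) x@diagnosticIndex)
#' @rdname accessors
setMethod("sampleTotals", "CloneTable", function(x) x@sampleTotals)
#' @rdname accessors
setMethod("annotation", "CloneTable", function(x) x@annotation)
#' @rdname accessors
setMethod("isAnnotated", "CloneTable", function(x) nrow(x@annotation) == length(x@sequences) && length(x@sequences) > 0 || (length(x@sequences) == 0 && ncol(x@annotation) > 0))

#' @rdname accessors
setMethod("signatures", "SignatureSet", function(x) x@signatures)
#' @rdname accessors
setMethod("sampleIndex", "SignatureSet", function(x) x@sampleIndex)

#' @rdname accessors
setMethod("kmers", "SignificantKmerSet", function(x) x@kmers)
#' @rdname accessors
setMethod("kmers", "KmerTable", function(x) rownames(x@counts))
#' @rdname accessors
setMethod("kmerCounts", "KmerTable", function(x) x@counts)

#' @rdname accessors
setMethod("germlineSegments", "GermlineDB", function(x) x@segments)
#' @rdname accessors
setMethod("annotationHits", "VdjAnnotation", function(x) x@hits)
#' @rdname accessors
setMethod("mrdTable", "MrdSeries", function(x) x@table)
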