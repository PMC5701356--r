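#' Smith-Waterman scoring parameters
#'
#' Holds the local-alignment scoring constants used throughout signature
#' correction, clone accumulation and germline annotation: match reward
#' \code{M}, mismatch penalty \code{MM}, linear insertion/deletion penalty
#' \code{IN}, and the length-ratio cutoff of the similarity threshold (a
#' pair whose shorter sequence is below \code{lengthRatio} of the longer is
#' always considered different).
#'
#' @slot match positive match reward (default 2).
#' @slot mismatch non-negative mismatch penalty (default 2).
#' @slot indel non-negative per-base gap penalty (default 3).
#' @slot lengthRatio cutoff in (0, 1), default 0.7.
#' @aliases ScoringParams
#' @exportClass ScoringParams
setClass("ScoringParams",
  representation(match = "numeric", mismatch = "numeric",
                 indel = "numeric", lengthRatio = "numeric"))

setValidity("ScoringParams", function(object) {
  msg <- character()
  ok1 <- function(x) length(x) == 1L && is.finite(x)
  if (!ok1(object@match) || object@match <= 0)
    msg <- c(msg, "'match' must be a single positive number")
  if (!ok1(object@mismatch) || object@mismatch < 0)
    msg <- c(msg, "'mismatch' must be a single non-negative number")
  if (!ok1(object@indel) || object@indel < 0)
    msg <- c(msg, "'indel' must be a single non-negative number")
  if (!ok1(object@lengthRatio) || object@lengthRatio <= 0 || object@lengthRatio >= 1)
    msg <- c(msg, "'lengthRatio' must lie strictly between 0 and 1")
  if (length(msg)) msg else TRUE
})

#' @param match,mismatch,indel,lengthRatio see slot documentation.
#' @return A \code{ScoringParams} object.
#' @rdname ScoringParams-class
#' @examples
#' scoringParams()             # the default M = MM = 2, IN = 3 scheme
#' scoringParams(indel = 2)
#' @export
scoringParams <- function(match = 2, mismatch = 2, indel = 3, lengthRatio = 0.7) {
  new("ScoringParams", match = match, mismatch = mismatch,
      indel = indel, lengthRatio = lengthRatio)
}

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf("ScoringParams: M=%g MM=%g IN=%g lengthRatio=%g\n",
              object@match, object@mismatch, object@indel, object@lengthRatio))
})

#' Multi-sample k-mer frequency table
#'
#' Maps every k-mer observed in any sample to its per-sample sliding-window
#' occurrence count. Row names are the k-mers, columns the samples in their
#' fixed index order.
#'
#' @slot k k-mer length; every row name has exactly this many characters.
#' @slot counts non-negative integer matrix, k-mers x samples.
#' @aliases KmerTable
#' @exportClass KmerTable
setClass("KmerTable", representation(k = "integer", counts = "matrix"))

setValidity("KmerTable", function(object) {
  msg <- character()
  cn <- object@counts
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a single positive integer")
  if (is.null(rownames(cn)) && nrow(cn) > 0)
    msg <- c(msg, "'counts' must have k-mer row names")
  else if (nrow(cn) > 0 && any(nchar(rownames(cn)) != object@k))
    msg <- c(msg, "every k-mer must have length k")
  if (length(cn) && (any(is.na(cn)) || any(cn < 0)))
    msg <- c(msg, "counts must be non-negative")
  if (ncol(cn) < 1L) msg <- c(msg, "at least one sample column is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable: %d k-mers of length %d across %d sample(s)\n",
              nrow(object@counts), object@k, ncol(object@counts)))
})

#' Significant k-mer set
#'
#' The k-mers whose per-sample counts differ by at least \code{tau} orders
#' of magnitude between some pair of samples (with the convention that a
#' count of zero against a count of at least \code{10^tau} also qualifies).
#'
#' @slot k k-mer length.
#' @slot tau the user significance threshold (orders of magnitude).
#' @slot kmers character vector of significant k-mers.
#' @aliases SignificantKmerSet
#' @exportClass SignificantKmerSet
setClass("SignificantKmerSet",
  representation(k = "integer", tau = "numeric", kmers = "character"))

setValidity("SignificantKmerSet", function(object) {
  msg <- character()
  if (!(length(object@tau) == 1L && object@tau > 0))
    msg <- c(msg, "'tau' must be a single positive number")
  if (length(object@kmers) && any(nchar(object@kmers) != object@k))
    msg <- c(msg, "every k-mer must have length k")
  if (anyDuplicated(object@kmers)) msg <- c(msg, "k-mers must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignificantKmerSet", function(object) {
  cat(sprintf("SignificantKmerSet: %d k-mer(s) of length %d (tau = %g)\n",
              length(object@kmers), object@k, object@tau))
})

#' Per-sample signature set
#'
#' Read signatures of one sample: each signature is the concatenation of
#' the maximal read stretches covered by significant k-mers, with its
#' frequency (number of contributing reads) and one exemplar full-length
#' read. \code{nEmpty} counts the reads that carried no significant k-mer.
#'
#' @slot sampleIndex 1-based sample index in the patient's series.
#' @slot signatures data.frame with columns \code{sequence},
#'   \code{frequency}, \code{exemplar}.
#' @slot nEmpty number of reads yielding an empty signature.
#' @aliases SignatureSet
#' @exportClass SignatureSet
setClass("SignatureSet",
  representation(sampleIndex = "integer", signatures = "data.frame",
                 nEmpty = "numeric"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  df <- object@signatures
  need <- c("sequence", "frequency", "exemplar")
  if (!all(need %in% names(df)))
    msg <- c(msg, "signatures need columns sequence, frequency, exemplar")
  else {
    if (nrow(df) && any(df$frequency < 1)) msg <- c(msg, "frequencies must be >= 1")
    if (nrow(df) && any(!nzchar(df$sequence))) msg <- c(msg, "sequences must be non-empty")
    if (anyDuplicated(df$sequence)) msg <- c(msg, "signature sequences must be unique")
  }
  if (length(object@sampleIndex) != 1L || object@sampleIndex < 1L)
    msg <- c(msg, "'sampleIndex' must be a single index >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: sample %d, %d signature(s), %g read(s) total, %g empty read(s)\n",
              object@sampleIndex, nrow(object@signatures),
              sum(object@signatures$frequency), object@nEmpty))
})

#' Multi-sample clone table
#'
#' Putative clonotypes with their per-sample read counts. A clone's
#' representative \code{sequence} is the signature that founded it; its
#' \code{exemplar} is a full-length read carrying that signature (used for
#' germline annotation and reporting). \code{sampleTotals} are the total
#' valid reads per sample, the denominators of relative abundances.
#'
#' @slot sequences clone signature sequences.
#' @slot exemplars exemplar full reads, parallel to \code{sequences}.
#' @slot counts numeric matrix, clones x samples.
#' @slot sampleLabels sample labels in index order.
#' @slot diagnosticIndex index of the diagnostic (baseline) sample.
#' @slot sampleTotals total reads per sample (NA when unknown).
#' @slot annotation zero-row data.frame until \code{\link{annotateClones}}
#'   fills the best V/D/J hits per clone.
#' @aliases CloneTable
#' @exportClass CloneTable
setClass("CloneTable",
  representation(sequences = "character", exemplars = "character",
                 counts = "matrix", sampleLabels = "character",
                 diagnosticIndex = "integer", sampleTotals = "numeric",
                 annotation = "data.frame"))

setValidity("CloneTable", function(object) {
  msg <- character()
  n <- length(object@sequences)
  ns <- length(object@sampleLabels)
  if (length(object@exemplars) != n) msg <- c(msg, "exemplars must parallel sequences")
  if (nrow(object@counts) != n || ncol(object@counts) != ns)
    msg <- c(msg, "counts must be clones x samples")
  if (n > 0 && any(rowSums(object@counts) <= 0))
    msg <- c(msg, "every clone needs a positive count somewhere")
  if (length(object@counts) && any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@diagnosticIndex) != 1L || is.na(object@diagnosticIndex) ||
      object@diagnosticIndex < 1L || object@diagnosticIndex > ns)
    msg <- c(msg, "diagnosticIndex out of range")
  if (length(object@sampleTotals) != ns)
    msg <- c(msg, "sampleTotals must have one entry per sample")
  if (nrow(object@annotation) && nrow(object@annotation) != n)
    msg <- c(msg, "annotation must have one row per clone (or none)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CloneTable", function(object) {
  cat(sprintf("CloneTable: %d clone(s) x %d sample(s) [diagnostic: %s]%s\n",
              length(object@sequences), length(object@sampleLabels),
              object@sampleLabels[object@diagnosticIndex],
              if (nrow(object@annotation)) ", annotated" else ""))
  if (length(object@sequences)) {
    m <- frequencyMatrix(object)
    print(utils::head(m, 6L))
    if (nrow(m) > 6L) cat("...\n")
  }
})

#' Germline V/D/J reference
#'
#' Germline gene segments grouped into the V, D and J classes, as parsed
#' from an IMGT GENE-DB-style FASTA by \code{\link{loadGermline}} or
#' generated by \code{\link{makeToyGermline}}.
#'
#' @slot segments data.frame with columns \code{gene}, \code{class}
#'   (one of "V", "D", "J") and \code{sequence}.
#' @aliases GermlineDB
#' @exportClass GermlineDB
setClass("GermlineDB", representation(segments = "data.frame"))

setValidity("GermlineDB", function(object) {
  df <- object@segments
  msg <- character()
  if (!all(c("gene", "class", "sequence") %in% names(df)))
    msg <- c(msg, "segments need columns gene, class, sequence")
  else {
    if (!all(df$class %in% c("V", "D", "J")))
      msg <- c(msg, "class must be one of V, D, J")
    if (nrow(df) && any(!nzchar(df$sequence)))
      msg <- c(msg, "sequences must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GermlineDB", function(object) {
  tb <- table(factor(object@segments$class, levels = c("V", "D", "J")))
  cat(sprintf("GermlineDB: %d V, %d D, %d J segment(s)\n", tb["V"], tb["D"], tb["J"]))
})

#' Ranked V/D/J annotation of one clone
#'
#' For each germline class, every segment's best local alignment against the
#' clone, ranked by identity (matched columns over matched + mismatched +
#' gapped columns of the local alignment) with alignment score as
#' tiebreaker.
#'
#' @slot hits data.frame with columns \code{class}, \code{gene},
#'   \code{identity}, \code{score}, \code{rank} (1 = best within class).
#' @aliases VdjAnnotation
#' @exportClass VdjAnnotation
setClass("VdjAnnotation", representation(hits = "data.frame"))

setMethod("show", "VdjAnnotation", function(object) {
  best <- object@hits[object@hits$rank == 1L, c("class", "gene", "identity", "score")]
  cat("VdjAnnotation (best hit per class):\n")
  print(best, row.names = FALSE)
})

#' Clone-filtering configuration
#'
#' Thresholds of the two-phase clone filter: Phase A keeps clones whose
#' diagnostic-sample read count is strictly greater than
#' \code{minDiagReads}; Phase B keeps clones whose best-hit germline
#' identity is strictly greater than \code{minIdentity} in all of V, D
#' and J simultaneously.
#'
#' @slot minDiagReads non-negative count threshold (default 100).
#' @slot minIdentity identity threshold in [0, 1] (default 0.80).
#' @aliases FilterConfig
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(minDiagReads = "numeric", minIdentity = "numeric"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (length(object@minDiagReads) != 1L || object@minDiagReads < 0)
    msg <- c(msg, "'minDiagReads' must be a single count >= 0")
  if (length(object@minIdentity) != 1L || object@minIdentity < 0 || object@minIdentity > 1)
    msg <- c(msg, "'minIdentity' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param minDiagReads,minIdentity see slot documentation.
#' @return A \code{FilterConfig} object.
#' @rdname FilterConfig-class
#' @export
filterConfig <- function(minDiagReads = 100, minIdentity = 0.80) {
  new("FilterConfig", minDiagReads = minDiagReads, minIdentity = minIdentity)
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf("FilterConfig: diagnostic reads > %g, V/D/J identities > %g\n",
              object@minDiagReads, object@minIdentity))
})

#' MRD series of one clone
#'
#' Per-sample relative abundance of a tracked clone and its MRD level
#' scaled so that the diagnostic sample sits exactly at \code{baseline}
#' (the ASO q-PCR-style anchor).
#'
#' @slot table data.frame with columns \code{sample}, \code{count},
#'   \code{total}, \code{abundance}, \code{level}, \code{flag}.
#' @slot baseline the diagnostic anchor value (> 0).
#' @slot cloneSequence the tracked clone's signature sequence.
#' @aliases MrdSeries
#' @exportClass MrdSeries
setClass("MrdSeries",
  representation(table = "data.frame", baseline = "numeric",
                 cloneSequence = "character"))

setMethod("show", "MrdSeries", function(object) {
  cat(sprintf("MrdSeries (baseline %g):\n", object@baseline))
  print(object@table, row.names = FALSE)
})
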