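#' Accumulate per-sample signature sets into a clone table
#'
#' Processes the corrected signature sets in sample order. For each
#' signature a similar clone is searched in the growing table using the
#' same similarity predicate as signature correction; if found, the
#' signature's frequency is added to that clone's entry for the current
#' sample, otherwise a new clone is created whose count vector is the
#' signature frequency at the current sample and 0 elsewhere. When several
#' clones are similar, the one with the highest alignment score wins (ties:
#' higher total clone frequency, then lexicographically smaller sequence).
#' A clone's representative sequence and exemplar never change after
#' insertion. Per-sample count totals are conserved from signatures to
#' clones.
#'
#' @param signatureSets ordered list of corrected \code{\link{SignatureSet}}
#'   objects, one per sample.
#' @param params a \code{\link{scoringParams}} object.
#' @param sampleLabels optional labels; default \code{S1..Sn}.
#' @param diagnosticIndex 1-based index of the diagnostic sample.
#' @return A \code{\link{CloneTable}} with \code{sampleTotals} equal to the
#'   signature frequency total plus the empty-read count of each sample
#'   (i.e. the number of valid reads per sample).
#' @export
accumulateClones <- function(signatureSets, params = scoringParams(),
                             sampleLabels = NULL, diagnosticIndex = 1L) {
  stopifnot(is.list(signatureSets), length(signatureSets) >= 1L)
  ok <- vapply(signatureSets, is, logical(1), "SignatureSet")
  if (!all(ok)) stop("'signatureSets' must be a list of SignatureSet objects")
  n <- length(signatureSets)
  if (is.null(sampleLabels)) sampleLabels <- paste0("S", seq_len(n))
  if (length(sampleLabels) != n)
    stop("inconsistent sample count: ", length(sampleLabels), " labels for ",
         n, " signature sets")
  sets <- lapply(signatureSets, function(s) {
    df <- s@signatures
    list(sequence = df$sequence, frequency = df$frequency, exemplar = df$exemplar)
  })
  res <- cpp_accumulate_clones(sets, n, params@match, params@mismatch,
                               params@indel, params@lengthRatio)
  totals <- vapply(signatureSets,
                   function(s) sum(s@signatures$frequency) + s@nEmpty,
                   numeric(1))
  counts <- res$counts
  if (!is.matrix(counts)) counts <- matrix(numeric(0), 0L, n)
  new("CloneTable", sequences = as.character(res$sequence),
      exemplars = as.character(res$exemplar), counts = counts,
      sampleLabels = as.character(sampleLabels),
      diagnosticIndex = as.integer(diagnosticIndex),
      sampleTotals = totals,
      annotation = data.frame())
}

#' Clone-by-sample frequency matrix
#'
#' Rows are clones ordered by descending frequency in the diagnostic
#' sample (ties broken lexicographically by sequence); a \code{Total} row
#' with per-sample count sums is appended. Row names are the clone
#' sequences.
#'
#' @param table a \code{\link{CloneTable}}.
#' @return Numeric matrix (clones + totals row) x samples.
#' @export
frequencyMatrix <- function(table) {
  stopifnot(is(table, "CloneTable"))
  m <- table@counts
  dimnames(m) <- list(table@sequences, table@sampleLabels)
  if (nrow(m)) {
    ord <- order(-m[, table@diagnosticIndex], rownames(m))
    m <- m[ord, , drop = FALSE]
  }
  rbind(m, Total = colSums(m))
}

#' Extract one clone from a table
#'
#' @param table a \code{\link{CloneTable}}.
#' @param i clone index (in storage order).
#' @return List with \code{sequence}, \code{exemplar}, \code{counts}
#'   (named per-sample vector) and, when annotated, \code{annotation}
#'   (one-row data.frame).
#' @export
cloneAt <- function(table, i) {
  stopifnot(is(table, "CloneTable"), i >= 1L, i <= nClones(table))
  out <- list(sequence = table@sequences[i], exemplar = table@exemplars[i],
              counts = setNames(table@counts[i, ], table@sampleLabels))
  if (nrow(table@annotation)) out$annotation <- table@annotation[i, , drop = FALSE]
  out
}

# Internal: subset a CloneTable's clones, preserving metadata.
.subsetClones <- function(table, keep) {
  new("CloneTable", sequences = table@sequences[keep],
      exemplars = table@exemplars[keep],
      counts = table@counts[keep, , drop = FALSE],
      sampleLabels = table@sampleLabels,
      diagnosticIndex = table@diagnosticIndex,
      sampleTotals = table@sampleTotals,
      annotation = if (nrow(table@annotation))
        table@annotation[keep, , drop = FALSE] else table@annotation)
}
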