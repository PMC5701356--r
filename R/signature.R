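#' Build the signature of one read
#'
#' Every k-mer of the read that belongs to the significant set marks its
#' covered positions; the signature is the concatenation, in read order, of
#' the maximal contiguous covered stretches (the union of the covered
#' intervals). A read carrying no significant k-mer yields the empty
#' string.
#'
#' Note one subtlety of this interval-union convention: for the read
#' \code{ATCCCGTC} with significant k-mers \{CCC, CCG, CGT\} (k = 3) the
#' covered positions are 3..7 and the signature is \code{"CCCGT"} — not the
#' shorter \code{"CCGT"} occasionally quoted for this example, which cannot
#' be reconciled with the positions those k-mers occupy.
#'
#' @param read a single DNA string.
#' @param psi a \code{\link{SignificantKmerSet}} or character vector of
#'   significant k-mers (all of length \code{k}).
#' @param k k-mer length used to build \code{psi}.
#' @return The signature string (possibly \code{""}).
#' @examples
#' buildSignature("ATCCCGTC", c("CCC", "CCG", "CGT"), 3)  # "CCCGT"
#' @export
buildSignature <- function(read, psi, k) {
  k <- .checkK(k)
  psi <- .psiKmers(psi, k)
  km <- extractKmers(read, k)
  hit <- km$kmer %in% psi
  if (!any(hit)) return("")
  covered <- logical(nchar(read))
  for (p in km$start[hit]) covered[p:(p + k - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  paste(substring(read, starts[r$values], ends[r$values]), collapse = "")
}

.psiKmers <- function(psi, k) {
  if (is(psi, "SignificantKmerSet")) {
    if (psi@k != k) stop("psi was built with k = ", psi@k, ", not ", k)
    psi <- psi@kmers
  }
  if (length(psi) && any(nchar(psi) != k))
    stop("significant k-mers must all have length k")
  psi
}

#' Collect the signature set of one sample
#'
#' Builds every read's signature (see \code{\link{buildSignature}}), pools
#' identical signatures with frequency equal to the number of contributing
#' reads, keeps the first read encountered as each signature's exemplar,
#' and counts reads yielding an empty signature. Signatures are ordered by
#' (frequency descending, sequence ascending).
#'
#' @param reads character vector of reads of the sample.
#' @param psi significant k-mer set (object or character vector).
#' @param k k-mer length.
#' @param sampleIndex 1-based index of this sample in the patient's series.
#' @return A \code{\link{SignatureSet}}.
#' @export
collectSignatures <- function(reads, psi, k, sampleIndex = 1L) {
  k <- .checkK(k)
  psi <- .psiKmers(psi, k)
  res <- cpp_collect_signatures(as.character(reads), as.character(psi), k)
  df <- data.frame(sequence = as.character(res$sequence),
                   frequency = as.numeric(res$frequency),
                   exemplar = as.character(res$exemplar),
                   exemplarIndex = as.integer(res$exemplar_index))
  df <- df[order(-df$frequency, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  new("SignatureSet", sampleIndex = as.integer(sampleIndex),
      signatures = df, nEmpty = as.numeric(res$n_empty))
}

#' Smith-Waterman local alignment score
#'
#' Best local-alignment score with +\code{M} per match, -\code{MM} per
#' mismatch and a linear gap penalty of -\code{IN} per inserted or deleted
#' base. \code{N} never counts as a match (it scores as a mismatch, even
#' against another \code{N}). Symmetric in its arguments.
#'
#' @param a,b non-empty DNA strings.
#' @param params a \code{\link{scoringParams}} object.
#' @return Non-negative integer score.
#' @examples
#' swScore("ACGT", "ACGT")   # 8 with the default M = 2
#' @export
swScore <- function(a, b, params = scoringParams()) {
  stopifnot(is(params, "ScoringParams"))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  cpp_sw_score(a, b, as.integer(params@match), as.integer(params@mismatch),
               as.integer(params@indel))
}

#' Length-dependent similarity threshold
#'
#' The score two sequences must strictly exceed to be called similar. When
#' the shorter length is below \code{lengthRatio} (default 0.7) of the
#' longer, the threshold equals \code{M * max(len)} — unattainable, so such
#' pairs are always different. Otherwise it is
#' \code{(M*4/5 - MM*2/50 - IN*2/10) * max(len)}; with the default
#' M = MM = 2, IN = 3 the coefficient is 0.92.
#'
#' @param lenA,lenB sequence lengths (>= 1).
#' @param params a \code{\link{scoringParams}} object.
#' @return The threshold (not rounded; compared as-is against integer
#'   scores).
#' @examples
#' similarityThreshold(10, 10)  # 9.2
#' similarityThreshold(10, 6)   # 20: the pair can never be similar
#' @export
similarityThreshold <- function(lenA, lenB, params = scoringParams()) {
  stopifnot(is(params, "ScoringParams"))
  if (lenA < 1 || lenB < 1) stop("lengths must be >= 1")
  cpp_sim_threshold(as.integer(lenA), as.integer(lenB), params@match,
                    params@mismatch, params@indel, params@lengthRatio)
}

#' Similarity predicate between two signatures
#'
#' \code{TRUE} iff the Smith-Waterman score of the two sequences is
#' strictly greater than their \code{\link{similarityThreshold}}.
#'
#' @param a,b signature sequences (character).
#' @param params a \code{\link{scoringParams}} object.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
areSimilar <- function(a, b, params = scoringParams()) {
  swScore(a, b, params) > similarityThreshold(nchar(a), nchar(b), params)
}

#' Correct a signature set by merging similar signatures
#'
#' Repeatedly merges similar signature pairs, always absorbing the
#' lower-frequency member into the higher-frequency one and summing their
#' frequencies, until no similar pair remains. The visit order is
#' deterministic: signatures ranked by (frequency descending, sequence
#' ascending) are greedily absorbed by the first higher-ranked similar
#' survivor. One such pass provably reaches a fixed point (the similarity
#' predicate ignores frequencies and is symmetric, and every surviving
#' pair has been tested), so correcting again changes nothing. Total
#' frequency is
#' conserved; the surviving sequence (and exemplar) of each merge is the
#' higher-ranked one's.
#'
#' @param set a \code{\link{SignatureSet}}.
#' @param params a \code{\link{scoringParams}} object.
#' @return The corrected \code{\link{SignatureSet}}.
#' @export
correctSignatures <- function(set, params = scoringParams()) {
  stopifnot(is(set, "SignatureSet"), is(params, "ScoringParams"))
  df <- set@signatures
  if (nrow(df) <= 1L) return(set)
  res <- cpp_correct_signatures(df$sequence, df$frequency, params@match,
                                params@mismatch, params@indel,
                                params@lengthRatio)
  out <- df[res$index, , drop = FALSE]
  out$frequency <- as.numeric(res$frequency)
  out <- out[order(-out$frequency, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  new("SignatureSet", sampleIndex = set@sampleIndex, signatures = out,
      nEmpty = set@nEmpty)
}

#' Serialize a signature set as TSV
#'
#' Columns: sequence, frequency, exemplar; one \code{#} header line.
#'
#' @param set a \code{\link{SignatureSet}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeSignatureSet <- function(set, path) {
  stopifnot(is(set, "SignatureSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#sequence\tfrequency\texemplar", con)
  df <- set@signatures
  if (nrow(df))
    writeLines(paste(df$sequence, df$frequency, df$exemplar, sep = "\t"), con)
  invisible(path)
}
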