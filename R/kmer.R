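#' Extract sliding-window k-mers from a read
#'
#' Enumerates every substring of length \code{k} of \code{read} together
#' with its 1-based start position, preserving read order. A read shorter
#' than \code{k} yields zero rows.
#'
#' @param read a single DNA string over \{A,C,G,T,N\}.
#' @param k k-mer length (positive integer).
#' @return data.frame with columns \code{kmer} and \code{start}.
#' @examples
#' extractKmers("ATCCCGTC", 3)
#' @export
extractKmers <- function(read, k) {
  .checkK(k)
  stopifnot(is.character(read), length(read) == 1L)
  len <- nchar(read)
  if (len < k) return(data.frame(kmer = character(0), start = integer(0)))
  start <- seq_len(len - k + 1L)
  data.frame(kmer = substring(read, start, start + k - 1L), start = start)
}

.checkK <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k))
    stop("'k' must be a single positive integer")
  invisible(as.integer(k))
}

.checkTau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  invisible(tau)
}

#' Count a sample's k-mer occurrences
#'
#' Counts the total number of sliding-window occurrences of every k-mer
#' across all reads of one sample (occurrences, not reads-containing: a
#' k-mer repeated within a read contributes each occurrence). The counts of
#' a sample therefore always sum to
#' \eqn{\sum_{reads} \max(len - k + 1, 0)}.
#'
#' @param reads character vector of DNA strings over \{A,C,G,T,N\}.
#' @param k k-mer length.
#' @return Named integer vector of counts, sorted by k-mer.
#' @examples
#' countSampleKmers(c("ATCCCGTC"), 3)
#' @export
countSampleKmers <- function(reads, k) {
  k <- .checkK(k)
  counts <- cpp_count_kmers(as.character(reads), k)
  counts[order(names(counts))]
}

#' Merge per-sample k-mer counts into a multi-sample table
#'
#' Builds the \code{\link{KmerTable}} whose row for k-mer \eqn{\alpha} is
#' the vector of its occurrence counts across the \eqn{n} samples, with 0
#' where a sample lacks the k-mer.
#'
#' @param perSampleCounts ordered list of named count vectors (one per
#'   sample), all built with the same \code{k}.
#' @param labels optional sample labels; defaults to names of the list or
#'   \code{S1..Sn}.
#' @return A \code{\link{KmerTable}}.
#' @export
mergeCounts <- function(perSampleCounts, labels = NULL) {
  stopifnot(is.list(perSampleCounts), length(perSampleCounts) >= 1L)
  n <- length(perSampleCounts)
  ks <- vapply(perSampleCounts, function(x) {
    if (length(x) == 0L) NA_integer_ else unique(nchar(names(x)))[1L]
  }, integer(1))
  widths <- unlist(lapply(perSampleCounts, function(x) unique(nchar(names(x)))))
  if (length(unique(widths)) > 1L)
    stop("per-sample maps were built with different k")
  k <- if (length(widths)) unique(widths) else NA_integer_
  if (is.na(k)) stop("cannot infer k from empty per-sample maps")
  if (is.null(labels)) {
    labels <- names(perSampleCounts)
    if (is.null(labels) || any(!nzchar(labels))) labels <- paste0("S", seq_len(n))
  }
  allk <- sort(unique(unlist(lapply(perSampleCounts, names))))
  m <- matrix(0L, nrow = length(allk), ncol = n, dimnames = list(allk, labels))
  for (i in seq_len(n)) {
    x <- perSampleCounts[[i]]
    if (length(x)) m[names(x), i] <- as.integer(x)
  }
  new("KmerTable", k = as.integer(k), counts = m)
}

#' Significance predicate on a k-mer frequency vector
#'
#' A k-mer is significant when some pair of samples \eqn{(i, j)} differs by
#' at least \code{tau} orders of magnitude:
#' \eqn{|log10(c_i) - log10(c_j)| \ge \tau} when both counts are non-zero,
#' or \eqn{log10(c) \ge \tau} for the non-zero count when the other is
#' zero. A single-sample vector is never significant (no pair exists).
#'
#' @param freqVector vector of non-negative per-sample counts.
#' @param tau positive significance threshold.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' isSignificant(c(1000, 2000, 25000), 1)   # TRUE: samples 1 and 3
#' isSignificant(c(50, 50), 1)              # FALSE
#' @export
isSignificant <- function(freqVector, tau) {
  .checkTau(tau)
  stopifnot(is.numeric(freqVector), length(freqVector) >= 1L, all(freqVector >= 0))
  if (length(freqVector) < 2L) return(FALSE)
  nz <- freqVector[freqVector > 0]
  if (length(nz) == 0L) return(FALSE)
  l <- log10(nz)
  if (length(nz) < length(freqVector) && max(l) >= tau) return(TRUE)
  length(nz) >= 2L && (max(l) - min(l)) >= tau
}

#' Select the significant k-mers of a table
#'
#' Applies \code{\link{isSignificant}} to every row of a
#' \code{\link{KmerTable}}.
#'
#' @param table a \code{\link{KmerTable}}.
#' @param tau positive significance threshold.
#' @return A \code{\link{SignificantKmerSet}}.
#' @export
significantKmers <- function(table, tau) {
  stopifnot(is(table, "KmerTable"))
  .checkTau(tau)
  if (nrow(table@counts) == 0L) stop("the k-mer table is empty")
  cn <- table@counts
  keep <- vapply(seq_len(nrow(cn)), function(i) isSignificant(cn[i, ], tau), logical(1))
  new("SignificantKmerSet", k = table@k, tau = tau,
      kmers = sort(rownames(cn)[keep]))
}

#' Streaming significant-k-mer selection over read sets
#'
#' Equivalent to counting every sample, merging, and calling
#' \code{\link{significantKmers}}, but computed in C++ without
#' materialising the full multi-sample table — the path used by
#' \code{\link{runPipeline}} on deep samples.
#'
#' @param sampleReads list of character vectors of reads, one per sample,
#'   in sample order.
#' @param k k-mer length (at most 42 for this streaming path).
#' @param tau positive significance threshold.
#' @return A \code{\link{SignificantKmerSet}}.
#' @export
significantKmersFromReads <- function(sampleReads, k, tau) {
  k <- .checkK(k)
  .checkTau(tau)
  stopifnot(is.list(sampleReads), length(sampleReads) >= 1L)
  km <- cpp_significant_kmers(lapply(sampleReads, as.character), k, tau)
  new("SignificantKmerSet", k = k, tau = tau, kmers = km)
}

#' Serialize / read a k-mer table as TSV
#'
#' The dialect is one header line starting with \code{#} naming the
#' columns, then \code{kmer<TAB>c1<TAB>...<TAB>cn} rows.
#'
#' @param table a \code{\link{KmerTable}}.
#' @param path file path.
#' @return \code{writeKmerTable} returns \code{path} invisibly;
#'   \code{readKmerTable} returns a \code{\link{KmerTable}}.
#' @export
writeKmerTable <- function(table, path) {
  stopifnot(is(table, "KmerTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#kmer", colnames(table@counts)), collapse = "\t"), con)
  if (nrow(table@counts)) {
    lines <- paste(rownames(table@counts),
                   apply(table@counts, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname writeKmerTable
#' @export
readKmerTable <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing '#' header line in ", path)
  labels <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1L]][-1L]
  if (length(readLines(path)) < 2L) {
    m <- matrix(0L, 0L, length(labels), dimnames = list(NULL, labels))
    return(new("KmerTable", k = 1L, counts = m))
  }
  df <- read.table(path, sep = "\t", skip = 1L, header = FALSE,
                   colClasses = c("character", rep("integer", length(labels))),
                   col.names = c("kmer", labels), check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$kmer
  storage.mode(m) <- "integer"
  new("KmerTable", k = if (nrow(df)) as.integer(nchar(df$kmer[1L])) else 1L,
      counts = m)
}
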