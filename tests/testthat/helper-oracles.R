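# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# Plain R dynamic-programming Smith-Waterman (linear gaps, N never matches).
oracleSw <- function(a, b, M = 2, MM = 2, IN = 3) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  H <- matrix(0, la + 1, lb + 1)
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    sc <- if (A[i] == B[j] && A[i] != "N") M else -MM
    H[i + 1, j + 1] <- max(0, H[i, j] + sc, H[i, j + 1] - IN, H[i + 1, j] - IN)
  }
  max(H)
}

# Literal three-case significance rule evaluated over every ordered pair.
oracleSignificant <- function(counts, tau) {
  n <- length(counts)
  if (n < 2) return(FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- counts[i]; cj <- counts[j]
    if (ci != 0 && cj != 0 && abs(log10(ci) - log10(cj)) >= tau) return(TRUE)
    if (ci == 0 && cj != 0 && log10(cj) >= tau) return(TRUE)
    if (ci != 0 && cj == 0 && log10(ci) >= tau) return(TRUE)
  }
  FALSE
}

# Position-wise interval-union signature.
oracleSignature <- function(read, psi, k) {
  len <- nchar(read)
  covered <- rep(FALSE, len)
  if (len >= k) for (p in seq_len(len - k + 1)) {
    if (substr(read, p, p + k - 1) %in% psi) covered[p:(p + k - 1)] <- TRUE
  }
  paste(strsplit(read, "")[[1]][covered], collapse = "")
}

# The printed two-branch threshold, written independently.
oracleThreshold <- function(la, lb, M = 2, MM = 2, IN = 3) {
  mx <- max(la, lb); mn <- min(la, lb)
  if (mx * 0.7 > mn) mx * M else (M * 4 / 5 - MM * 2 / 50 - IN * 2 / 10) * mx
}

randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small ready-made germline for annotation tests.
testGermline <- function(seed = 101) {
  lines <- makeToyGermline(seed)
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  loadGermline(tf)
}

makeSignatureSet <- function(sequences, frequencies, sampleIndex = 1L,
                             exemplars = sequences, nEmpty = 0) {
  new("SignatureSet", sampleIndex = as.integer(sampleIndex),
      signatures = data.frame(sequence = sequences,
                              frequency = as.numeric(frequencies),
                              exemplar = exemplars),
      nEmpty = as.numeric(nEmpty))
}

makeCloneTable <- function(counts, sequences = NULL, diagnosticIndex = 1L,
                           totals = NULL, annotation = data.frame()) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(sequences))
    sequences <- vapply(seq_len(n), function(i) {
      set.seed(1000 + i); randomDna(40)
    }, character(1))
  if (is.null(totals)) totals <- colSums(counts)
  new("CloneTable", sequences = sequences, exemplars = sequences,
      counts = counts, sampleLabels = paste0("S", seq_len(ncol(counts))),
      diagnosticIndex = as.integer(diagnosticIndex),
      sampleTotals = as.numeric(totals), annotation = annotation)
}
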