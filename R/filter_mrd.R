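#' Phase-A clone filter: diagnostic read count
#'
#' Retains exactly the clones whose read count in the diagnostic sample is
#' strictly greater than \code{minDiagReads} (default 100): low-frequency
#' clonotypes are prudentially not considered representative of the
#' disease. The threshold is an absolute read count; 100 reads corresponds
#' to the commonly used 5%-of-reads rationale at the depths this filter
#' was designed for.
#'
#' @param table a \code{\link{CloneTable}}.
#' @param config a \code{\link{filterConfig}} object.
#' @return The filtered \code{\link{CloneTable}} (idempotent).
#' @export
phaseA <- function(table, config = filterConfig()) {
  stopifnot(is(table, "CloneTable"), is(config, "FilterConfig"))
  keep <- table@counts[, table@diagnosticIndex] > config@minDiagReads
  .subsetClones(table, keep)
}

#' Phase-B clone filter: germline homology
#'
#' Retains the clones whose best-hit identity is strictly greater than
#' \code{minIdentity} (default 0.80) in all three classes V, D and J
#' simultaneously. The table must be annotated first.
#'
#' @param table an annotated \code{\link{CloneTable}}.
#' @param config a \code{\link{filterConfig}} object.
#' @return The filtered \code{\link{CloneTable}} (idempotent).
#' @export
phaseB <- function(table, config = filterConfig()) {
  stopifnot(is(table, "CloneTable"), is(config, "FilterConfig"))
  if (!isAnnotated(table))
    stop("the clone table is not annotated; run annotateClones() first")
  ann <- table@annotation
  keep <- ann$v_identity > config@minIdentity &
          ann$d_identity > config@minIdentity &
          ann$j_identity > config@minIdentity
  .subsetClones(table, keep)
}

#' The major clone of a table
#'
#' The clone with the highest diagnostic-sample read count; ties broken
#' lexicographically by sequence.
#'
#' @param table a non-empty \code{\link{CloneTable}}.
#' @return The clone as returned by \code{\link{cloneAt}}.
#' @export
majorClone <- function(table) {
  stopifnot(is(table, "CloneTable"))
  if (nClones(table) == 0L) stop("no clones in the table: major clone not found")
  d <- table@counts[, table@diagnosticIndex]
  ord <- order(-d, table@sequences)
  cloneAt(table, ord[1L])
}

#' MRD series of a tracked clone
#'
#' Relative abundance per sample is the clone's read count divided by the
#' sample's total reads; the scaled MRD level is
#' \code{baseline * abundance / abundance[diagnostic]}, so the diagnostic
#' sample sits exactly at \code{baseline} (the ASO q-PCR-style anchor set
#' by the tumour infiltration at diagnosis, e.g. 1E+00 or 1E-01). A sample
#' where the clone is absent gets level 0 and flag \code{"not_detected"};
#' a sample with zero total reads gets \code{NA} values and flag
#' \code{"undefined"}.
#'
#' @param table a \code{\link{CloneTable}} with known \code{sampleTotals}.
#' @param clone a clone as returned by \code{\link{majorClone}} /
#'   \code{\link{cloneAt}}, or a clone sequence present in the table;
#'   defaults to the major clone.
#' @param baseline positive diagnostic anchor (default 1).
#' @return An \code{\link{MrdSeries}}.
#' @export
mrdSeries <- function(table, clone = majorClone(table), baseline = 1) {
  stopifnot(is(table, "CloneTable"))
  if (!(is.numeric(baseline) && length(baseline) == 1L && baseline > 0))
    stop("'baseline' must be a single positive number")
  if (is.character(clone)) {
    i <- match(clone, table@sequences)
    if (is.na(i)) stop("clone sequence not found in the table")
    clone <- cloneAt(table, i)
  }
  counts <- as.numeric(clone$counts)
  totals <- table@sampleTotals
  if (any(is.na(totals)))
    stop("per-sample total read counts are unknown; cannot compute abundances")
  abundance <- ifelse(totals > 0, counts / totals, NA_real_)
  di <- table@diagnosticIndex
  aDiag <- abundance[di]
  if (is.na(aDiag) || aDiag <= 0)
    stop("the tracked clone has no reads in the diagnostic sample")
  level <- baseline * abundance / aDiag
  level[di] <- baseline
  flag <- rep("detected", length(counts))
  flag[!is.na(abundance) & counts == 0] <- "not_detected"
  flag[totals == 0] <- "undefined"
  df <- data.frame(sample = table@sampleLabels, count = counts,
                   total = totals, abundance = abundance, level = level,
                   flag = flag)
  new("MrdSeries", table = df, baseline = baseline,
      cloneSequence = clone$sequence)
}

#' Export an MRD series
#'
#' TSV columns: sample, count, total, abundance, level, flag; the JSON
#' mirror additionally records the baseline and the tracked clone
#' sequence.
#'
#' @param series an \code{\link{MrdSeries}}.
#' @param path output TSV path; the JSON mirror gets extension
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
writeMrdSeries <- function(series, path) {
  stopifnot(is(series, "MrdSeries"))
  write.table(series@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonPath <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(baseline = series@baseline, clone = series@cloneSequence,
         series = series@table),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
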