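#' Read amplicon reads from FASTQ or FASTA
#'
#' Accepts 4-line FASTQ (quality ignored) or FASTA, plain or
#' gzip-compressed; the format is taken from the file extension and falls
#' back to sniffing the first character. Reads are upper-cased; reads
#' containing characters outside \{A,C,G,T,N\} are skipped with a warning
#' reporting their number.
#'
#' @param path input file.
#' @param sample label used in error and warning messages.
#' @return Character vector of valid reads.
#' @export
readSampleReads <- function(path, sample = basename(path)) {
  if (!file.exists(path))
    stop("cannot read sample '", sample, "': file not found: ", path)
  base <- sub("\\.(gz|bz2|xz)$", "", path)
  fmt <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) "fastq"
         else if (grepl("\\.(fasta|fa|fna)$", base, ignore.case = TRUE)) "fasta"
         else {
    con <- gzfile(path, "rt")
    first <- tryCatch(readLines(con, n = 1L), finally = close(con))
    if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  }
  seqs <- tryCatch(Biostrings::readBStringSet(path, format = fmt),
                   error = function(e)
                     stop("cannot read sample '", sample, "': ",
                          conditionMessage(e), call. = FALSE))
  reads <- toupper(as.character(seqs))
  names(reads) <- NULL
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warning(sum(bad), " read(s) with characters outside {A,C,G,T,N} ",
            "skipped in sample '", sample, "'")
    reads <- reads[!bad]
  }
  reads
}

#' Write the clone report
#'
#' TSV with the fixed column order Signature (the clone's signature
#' sequence), Clone (its representative full read), V-gene, V-identity,
#' D-gene, D-identity, J-gene, J-identity, then one frequency column per
#' sample labelled by sample name. Clones are ordered by descending
#' diagnostic frequency. A JSON mirror (same path with extension
#' \code{.json}) carries the rows plus the sample labels, diagnostic
#' index and per-sample totals so the table can be round-tripped with
#' \code{\link{readCloneReport}}.
#'
#' @param table a \code{\link{CloneTable}} (annotation columns are NA when
#'   the table has not been annotated).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCloneReport <- function(table, path) {
  stopifnot(is(table, "CloneTable"))
  n <- nClones(table)
  ord <- if (n) order(-table@counts[, table@diagnosticIndex], table@sequences)
         else integer(0)
  ann <- if (isAnnotated(table) && n) table@annotation[ord, , drop = FALSE]
         else data.frame(v_gene = rep(NA_character_, n),
                         v_identity = rep(NA_real_, n),
                         d_gene = rep(NA_character_, n),
                         d_identity = rep(NA_real_, n),
                         j_gene = rep(NA_character_, n),
                         j_identity = rep(NA_real_, n))
  freq <- table@counts[ord, , drop = FALSE]
  colnames(freq) <- table@sampleLabels
  df <- cbind(
    data.frame(Signature = table@sequences[ord],
               Clone = table@exemplars[ord],
               `V-gene` = ann$v_gene, `V-identity` = ann$v_identity,
               `D-gene` = ann$d_gene, `D-identity` = ann$d_identity,
               `J-gene` = ann$j_gene, `J-identity` = ann$j_identity,
               check.names = FALSE),
    as.data.frame(freq, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample_labels = table@sampleLabels,
         diagnostic_index = table@diagnosticIndex,
         sample_totals = table@sampleTotals,
         annotated = isAnnotated(table),
         clones = df),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a clone report's JSON mirror back into a CloneTable
#'
#' @param jsonPath path of the JSON mirror written by
#'   \code{\link{writeCloneReport}}.
#' @return A \code{\link{CloneTable}}.
#' @export
readCloneReport <- function(jsonPath) {
  x <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  labels <- as.character(x$sample_labels)
  cl <- x$clones
  if (is.null(cl) || length(cl) == 0L || nrow(as.data.frame(cl)) == 0L) {
    counts <- matrix(numeric(0), 0L, length(labels))
    return(new("CloneTable", sequences = character(0),
               exemplars = character(0), counts = counts,
               sampleLabels = labels,
               diagnosticIndex = as.integer(x$diagnostic_index),
               sampleTotals = as.numeric(x$sample_totals),
               annotation = data.frame()))
  }
  cl <- as.data.frame(cl, check.names = FALSE)
  counts <- as.matrix(cl[, labels, drop = FALSE])
  ann <- if (isTRUE(x$annotated))
    data.frame(v_gene = cl$`V-gene`, v_identity = cl$`V-identity`,
               d_gene = cl$`D-gene`, d_identity = cl$`D-identity`,
               j_gene = cl$`J-gene`, j_identity = cl$`J-identity`)
  else data.frame()
  new("CloneTable", sequences = as.character(cl$Signature),
      exemplars = as.character(cl$Clone), counts = unname(counts),
      sampleLabels = labels, diagnosticIndex = as.integer(x$diagnostic_index),
      sampleTotals = as.numeric(x$sample_totals), annotation = ann)
}
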