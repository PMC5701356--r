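#' Load a germline V/D/J reference from FASTA
#'
#' Accepts the IMGT GENE-DB header dialect (pipe-separated fields with the
#' gene name in field 2, e.g. \code{>X|IGHV1-2*01|Homo sapiens|F|V-REGION|...})
#' as well as plain headers consisting of the gene name alone. The gene
#' class is inferred from the 4th character of the gene name (V, D or J).
#' Sequences are upper-cased, IMGT alignment gaps (dots) are stripped, and
#' ambiguity codes other than N are converted to N (with a message giving
#' the count). Segments whose class cannot be inferred are skipped with a
#' warning; an empty class is a hard error.
#'
#' @param path FASTA file (plain or gzip-compressed).
#' @return A \code{\link{GermlineDB}}.
#' @export
loadGermline <- function(path) {
  if (!file.exists(path)) stop("germline FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in germline FASTA: ", path)
  headers <- names(seqs)
  gene <- vapply(headers, function(h) {
    fields <- strsplit(h, "|", fixed = TRUE)[[1L]]
    if (length(fields) >= 2L) trimws(fields[2L]) else trimws(fields[1L])
  }, character(1), USE.NAMES = FALSE)
  cls <- toupper(substr(gene, 4L, 4L))
  usable <- cls %in% c("V", "D", "J") & nzchar(gene)
  if (any(!usable)) {
    warning(sum(!usable), " segment(s) with unparseable headers skipped: ",
            paste(utils::head(headers[!usable], 3L), collapse = ", "))
  }
  sq <- toupper(gsub("[.\\s-]", "", as.character(seqs), perl = TRUE))
  nonstd <- gsub("[ACGTN]", "", sq)
  if (any(nzchar(nonstd))) {
    message("converted ", sum(nchar(nonstd)),
            " ambiguity base(s) to N in germline sequences")
    sq <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", sq)
  }
  df <- data.frame(gene = gene[usable], class = cls[usable],
                   sequence = sq[usable])
  df <- df[nzchar(df$sequence), , drop = FALSE]
  found <- unique(df$class)
  missing <- setdiff(c("V", "D", "J"), found)
  if (length(missing))
    stop("no usable germline segments in class(es) ",
         paste(missing, collapse = ", "), "; classes found: ",
         if (length(found)) paste(found, collapse = ", ") else "none")
  rownames(df) <- NULL
  new("GermlineDB", segments = df)
}

# Internal: local alignment of a clone against one segment; returns the
# identity over the locally aligned region (matches / aligned columns).
.alignSegment <- function(cloneSeq, segSeq, params) {
  cpp_sw_align(cloneSeq, segSeq, as.integer(params@match),
               as.integer(params@mismatch), as.integer(params@indel))
}

#' Annotate one clone against the germline reference
#'
#' For each class (V, D, J) independently, computes a Smith-Waterman local
#' alignment of the clone against every segment of the class and ranks the
#' hits by identity — matched columns divided by matched + mismatched +
#' gapped columns of the local alignment — with the alignment score, then
#' the gene name, as tiebreakers. \code{N} positions never count as
#' matches. The D search is restricted to the clone region between the
#' best V and best J local alignments (with a small margin) when both
#' exist and leave room, mirroring V(D)J architecture; otherwise the full
#' clone is searched.
#'
#' @param cloneSequence non-empty DNA string (typically the clone's
#'   exemplar read, which carries the V/J context the signature may lack).
#' @param db a \code{\link{GermlineDB}}.
#' @param params a \code{\link{scoringParams}} object.
#' @param bothStrands also check the reverse complement and keep the
#'   better-scoring orientation per segment (off by default: amplicon
#'   orientation is assumed fixed by the primers).
#' @return A \code{\link{VdjAnnotation}}.
#' @export
annotateClone <- function(cloneSequence, db, params = scoringParams(),
                          bothStrands = FALSE) {
  stopifnot(is(db, "GermlineDB"), is(params, "ScoringParams"))
  if (!is.character(cloneSequence) || length(cloneSequence) != 1L ||
      !nzchar(cloneSequence))
    stop("'cloneSequence' must be a single non-empty DNA string")
  segs <- db@segments
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(cloneSequence)))
    cands <- c(cloneSequence, rc)
  } else {
    cands <- cloneSequence
  }

  alignClass <- function(cls, region) {
    sub <- segs[segs$class == cls, , drop = FALSE]
    hits <- lapply(seq_len(nrow(sub)), function(i) {
      best <- NULL
      for (qs in region) {
        al <- .alignSegment(qs, sub$sequence[i], params)
        if (is.null(best) || al$score > best$score) best <- al
      }
      data.frame(class = cls, gene = sub$gene[i], identity = best$identity,
                 score = best$score, matches = best$matches,
                 q_start = best$a_start, q_end = best$a_end)
    })
    df <- do.call(rbind, hits)
    df <- df[order(-df$identity, -df$score, df$gene), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  }

  vhits <- alignClass("V", cands)
  jhits <- alignClass("J", cands)

  # D search region: between the best V and J footprints on the clone.
  dRegion <- cands
  if (!bothStrands) {
    vEnd <- vhits$q_end[1L]
    jStart <- jhits$q_start[1L]
    margin <- 6L
    lo <- max(1L, vEnd - margin)
    hi <- min(nchar(cloneSequence), jStart + margin)
    if (vhits$score[1L] > 0 && jhits$score[1L] > 0 && hi - lo + 1L >= 5L)
      dRegion <- substr(cloneSequence, lo, hi)
  }
  dhits <- alignClass("D", dRegion)

  new("VdjAnnotation", hits = rbind(vhits, dhits, jhits))
}

#' Best hit of one class
#'
#' @param ann a \code{\link{VdjAnnotation}}.
#' @param cls one of \code{"V"}, \code{"D"}, \code{"J"}.
#' @return One-row data.frame (gene, identity, score).
#' @export
bestHit <- function(ann, cls) {
  stopifnot(is(ann, "VdjAnnotation"), cls %in% c("V", "D", "J"))
  h <- ann@hits
  h[h$class == cls & h$rank == 1L, c("gene", "identity", "score"), drop = FALSE]
}

#' Annotate every clone of a table
#'
#' Runs \code{\link{annotateClone}} on each clone's exemplar read (falling
#' back to the signature sequence when no exemplar is available) and
#' stores the best hit per class in the table's annotation.
#'
#' @param table a \code{\link{CloneTable}}.
#' @param db a \code{\link{GermlineDB}}.
#' @param params a \code{\link{scoringParams}} object.
#' @param bothStrands see \code{\link{annotateClone}}.
#' @return The annotated \code{\link{CloneTable}}.
#' @export
annotateClones <- function(table, db, params = scoringParams(),
                           bothStrands = FALSE) {
  stopifnot(is(table, "CloneTable"), is(db, "GermlineDB"))
  n <- nClones(table)
  cols <- c("v_gene", "v_identity", "d_gene", "d_identity", "j_gene", "j_identity")
  if (n == 0L) {
    ann <- as.data.frame(setNames(
      list(character(0), numeric(0), character(0), numeric(0),
           character(0), numeric(0)), cols))
    table@annotation <- ann
    return(table)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    qs <- table@exemplars[i]
    if (is.na(qs) || !nzchar(qs)) qs <- table@sequences[i]
    a <- annotateClone(qs, db, params, bothStrands)
    bv <- bestHit(a, "V"); bd <- bestHit(a, "D"); bj <- bestHit(a, "J")
    rows[[i]] <- data.frame(v_gene = bv$gene, v_identity = bv$identity,
                            d_gene = bd$gene, d_identity = bd$identity,
                            j_gene = bj$gene, j_identity = bj$identity)
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  table@annotation <- ann
  validObject(table)
  table
}
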