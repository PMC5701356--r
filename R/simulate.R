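# Synthetic VDJ-rearranged amplicon generator. Everything is driven by R's
# RNG so a seed fixes the full output byte-for-byte; helpers save and
# restore .Random.seed so simulation never perturbs the caller's stream.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.BASES <- c("A", "C", "G", "T")

# n random DNA strings with the given lengths (0 allowed), one RNG draw per
# base.
.randomBases <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  bases <- sample(.BASES, total, replace = TRUE)
  out <- rep("", length(lengths))
  idx <- rep.int(seq_along(lengths), lengths)
  pieces <- vapply(split(bases, factor(idx, levels = seq_along(lengths))),
                   paste, character(1), collapse = "")
  out[as.integer(names(pieces))] <- pieces
  out
}

#' Generate a deterministic toy germline reference
#'
#' Produces a small synthetic germline with 6 V (~250 nt), 5 D (15-30 nt)
#' and 5 J (~50 nt) segments under IMGT-dialect FASTA headers. Segments
#' are independent random sequences, so pairwise V identities stay well
#' below 90% and assignments are unambiguous. The same seed always yields
#' byte-identical output.
#'
#' @param seed integer seed.
#' @param path optional file path; when given the FASTA is written there.
#' @return Character vector of FASTA lines (invisibly when \code{path} is
#'   given).
#' @export
makeToyGermline <- function(seed = 1L, path = NULL) {
  lines <- .withSeed(seed, {
    vLens <- sample(240:260, 6L, replace = TRUE)
    dLens <- sample(15:30, 5L, replace = TRUE)
    jLens <- sample(48:55, 5L, replace = TRUE)
    vSeq <- .randomBases(vLens)
    dSeq <- .randomBases(dLens)
    jSeq <- .randomBases(jLens)
    hdr <- function(gene, region)
      sprintf(">SYN|%s|Homo sapiens|F|%s|synthetic", gene, region)
    c(rbind(hdr(sprintf("IGHV%d-1*01", seq_along(vSeq)), "V-REGION"), vSeq),
      rbind(hdr(sprintf("IGHD%d-1*01", seq_along(dSeq)), "D-REGION"), dSeq),
      rbind(hdr(sprintf("IGHJ%d*01", seq_along(jSeq)), "J-REGION"), jSeq))
  })
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Internal: GermlineDB from FASTA lines without touching disk.
.germlineFromLines <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  loadGermline(tf)
}

#' Simulate one VDJ rearrangement
#'
#' Joins a V segment trimmed at its 3' end, a random N1 insert, a D
#' segment trimmed at both ends, a random N2 insert, and a J segment
#' trimmed at its 5' end — the junctional deletions and random
#' nucleotide insertions that make each rearrangement clone-specific.
#' Insert bases are drawn from the current RNG stream.
#'
#' @param db a \code{\link{GermlineDB}}.
#' @param v,d,j gene names of the segments to use.
#' @param vTrim,d5Trim,d3Trim,jTrim junctional deletion lengths (>= 0).
#' @param n1,n2 inserted nucleotide counts (>= 0).
#' @return List with \code{sequence} and the generating choices.
#' @export
simulateRearrangement <- function(db, v, d, j, vTrim = 3L, d5Trim = 2L,
                                  d3Trim = 2L, jTrim = 3L, n1 = 4L, n2 = 4L) {
  stopifnot(is(db, "GermlineDB"))
  segs <- db@segments
  pick <- function(gene, cls) {
    i <- which(segs$gene == gene & segs$class == cls)
    if (length(i) != 1L) stop("segment not found in class ", cls, ": ", gene)
    segs$sequence[i]
  }
  vs <- pick(v, "V"); ds <- pick(d, "D"); js <- pick(j, "J")
  if (vTrim < 0 || d5Trim < 0 || d3Trim < 0 || jTrim < 0 || n1 < 0 || n2 < 0)
    stop("trims and insert lengths must be >= 0")
  if (vTrim >= nchar(vs)) stop("V trim (", vTrim, ") leaves no V sequence")
  if (d5Trim + d3Trim >= nchar(ds)) stop("D trims leave no D sequence")
  if (jTrim >= nchar(js)) stop("J trim (", jTrim, ") leaves no J sequence")
  ins <- .randomBases(c(n1, n2))
  seqn <- paste0(substr(vs, 1L, nchar(vs) - vTrim), ins[1L],
                 substr(ds, d5Trim + 1L, nchar(ds) - d3Trim), ins[2L],
                 substr(js, jTrim + 1L, nchar(js)))
  list(sequence = seqn, v = v, d = d, j = j,
       vTrim = vTrim, d5Trim = d5Trim, d3Trim = d3Trim, jTrim = jTrim,
       n1 = n1, n2 = n2)
}

# Internal: m fresh random rearrangements (the polyclonal background; each
# read is its own unique junction, so no background clonotype can exceed
# trivial frequency).
.randomRearrangements <- function(db, m) {
  if (m == 0L) return(character(0))
  segs <- db@segments
  vdf <- segs[segs$class == "V", , drop = FALSE]
  ddf <- segs[segs$class == "D", , drop = FALSE]
  jdf <- segs[segs$class == "J", , drop = FALSE]
  vi <- sample.int(nrow(vdf), m, replace = TRUE)
  di <- sample.int(nrow(ddf), m, replace = TRUE)
  ji <- sample.int(nrow(jdf), m, replace = TRUE)
  vTrim <- sample(0:6, m, replace = TRUE)
  d5 <- sample(0:5, m, replace = TRUE)
  d3 <- sample(0:5, m, replace = TRUE)
  jTrim <- sample(0:6, m, replace = TRUE)
  n1 <- sample(0:8, m, replace = TRUE)
  n2 <- sample(0:8, m, replace = TRUE)
  vs <- vdf$sequence[vi]; ds <- ddf$sequence[di]; js <- jdf$sequence[ji]
  dLen <- nchar(ds)
  over <- d5 + d3 >= dLen           # keep at least one D base
  d3[over] <- pmax(0L, dLen[over] - d5[over] - 1L)
  ins1 <- .randomBases(n1)
  ins2 <- .randomBases(n2)
  paste0(substr(vs, 1L, nchar(vs) - vTrim), ins1,
         substr(ds, d5 + 1L, dLen - d3), ins2,
         substr(js, jTrim + 1L, nchar(js)))
}

#' Simulate one amplicon sample
#'
#' Draws each read's origin (one of the defined clones, or a fresh unique
#' polyclonal rearrangement) according to the clone fractions, then applies
#' per-base substitution errors followed by per-base N-masking. Uses the
#' current RNG stream (wrap in \code{set.seed} or use
#' \code{\link{dilutionSeries}} for reproducible output).
#'
#' @param db a \code{\link{GermlineDB}}.
#' @param cloneSequences character vector of clone rearrangement sequences.
#' @param fractions per-clone read fractions (summing to <= 1; the
#'   remainder is polyclonal background).
#' @param nReads number of reads to generate (exact).
#' @param subRate per-base substitution error rate in [0, 1].
#' @param nRate marginal per-base N-masking probability in [0, 1] (the
#'   degraded-quality regime is emulated by raising this).
#' @param nRunLength 1 (default) masks bases independently; larger values
#'   group the masking into runs of this length — localized quality
#'   crashes — while keeping the same marginal per-base rate.
#' @return List with \code{reads} (character), \code{assignment} (integer,
#'   0 = background), and \code{cloneCounts} (true reads per clone).
#' @export
simulateSample <- function(db, cloneSequences, fractions, nReads,
                           subRate = 0.005, nRate = 0, nRunLength = 1L) {
  stopifnot(is(db, "GermlineDB"), length(cloneSequences) == length(fractions))
  if (any(fractions < 0) || sum(fractions) > 1)
    stop("clone fractions must be non-negative and sum to <= 1")
  nReads <- as.integer(nReads)
  assignment <- sample.int(length(fractions) + 1L, nReads, replace = TRUE,
                           prob = c(1 - sum(fractions), fractions)) - 1L
  reads <- character(nReads)
  for (ci in seq_along(cloneSequences))
    reads[assignment == ci] <- cloneSequences[ci]
  nBg <- sum(assignment == 0L)
  reads[assignment == 0L] <- .randomRearrangements(db, nBg)
  reads <- as.character(cpp_mutate_reads(reads, subRate, nRate,
                                         as.integer(nRunLength)))
  list(reads = reads, assignment = assignment,
       cloneCounts = tabulate(assignment, nbins = length(fractions)))
}

#' Simulate a dilution series with one spiked clone
#'
#' Generates one sample per entry of \code{fractions}, all sharing the same
#' spiked clone (a rearrangement drawn once from the toy or supplied
#' germline) on top of fresh polyclonal background. The first sample is
#' conventionally the diagnostic. Fully deterministic under \code{seed}.
#'
#' @param fractions spiked-clone read fraction per sample (first entry =
#'   diagnostic). Default \code{c(0.5, 0.1, 0.01, 0.001)}: a
#'   moderately-infiltrated diagnostic followed by ten-fold dilutions.
#' @param nReads reads per sample.
#' @param subRate,nRate,nRunLength see \code{\link{simulateSample}};
#'   a degraded-quality regime is typically emulated with
#'   \code{nRate = 0.2, nRunLength = 30}.
#' @param seed integer seed fixing the entire series.
#' @param db optional \code{\link{GermlineDB}}; default
#'   \code{makeToyGermline(seed)}.
#' @param dir optional output directory; when given, writes
#'   \code{sample_<i>.fastq} files plus a \code{truth.json} manifest and
#'   returns their paths.
#' @return List with \code{clone} (the spiked rearrangement and its
#'   generating segments), \code{samples} (per-sample results of
#'   \code{\link{simulateSample}}), \code{fractions}, \code{labels},
#'   \code{germline}, and (with \code{dir}) \code{files} and
#'   \code{manifest}.
#' @export
dilutionSeries <- function(fractions = c(0.5, 0.1, 0.01, 0.001),
                           nReads = 1e5, subRate = 0.005, nRate = 0,
                           nRunLength = 1L, seed = 1L, db = NULL,
                           dir = NULL) {
  if (any(fractions <= 0) || any(fractions > 1))
    stop("fractions must lie in (0, 1]")
  toyLines <- NULL
  if (is.null(db)) {
    toyLines <- makeToyGermline(seed)
    db <- .germlineFromLines(toyLines)
  }
  out <- .withSeed(seed, {
    segs <- db@segments
    vg <- segs$gene[segs$class == "V"]
    dg <- segs$gene[segs$class == "D"]
    jg <- segs$gene[segs$class == "J"]
    clone <- simulateRearrangement(
      db, sample(vg, 1L), sample(dg, 1L), sample(jg, 1L),
      vTrim = sample(0:6, 1L), d5Trim = sample(0:4, 1L),
      d3Trim = sample(0:4, 1L), jTrim = sample(0:6, 1L),
      n1 = sample(3:8, 1L), n2 = sample(3:8, 1L))
    samples <- lapply(fractions, function(f)
      simulateSample(db, clone$sequence, f, nReads, subRate, nRate,
                     nRunLength))
    list(clone = clone, samples = samples)
  })
  labels <- c("diagnostic",
              if (length(fractions) > 1L)
                paste0("fu", seq_len(length(fractions) - 1L)))
  res <- list(clone = out$clone, samples = out$samples,
              fractions = fractions, labels = labels, germline = db,
              nReads = nReads, subRate = subRate, nRate = nRate,
              nRunLength = nRunLength, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, sprintf("sample_%d.fastq", seq_along(fractions)))
    for (i in seq_along(files)) {
      ids <- sprintf("%s_read%d", labels[i], seq_len(nReads))
      writeFastq(out$samples[[i]]$reads, files[i], ids)
    }
    gl <- file.path(dir, "germline.fasta")
    if (is.null(toyLines)) {
      segs <- db@segments
      toyLines <- as.vector(rbind(paste0(">", segs$gene), segs$sequence))
    }
    writeLines(toyLines, gl)
    manifest <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(clone = out$clone, fractions = fractions, labels = labels,
           n_reads = nReads, sub_rate = subRate, n_rate = nRate,
           n_run_length = nRunLength, seed = seed,
           true_clone_counts = vapply(out$samples, function(s)
             s$cloneCounts[1L], numeric(1))),
      manifest, auto_unbox = TRUE, digits = NA)
    res$files <- setNames(files, labels)
    res$germlineFile <- gl
    res$manifest <- manifest
  }
  res
}

#' Write reads as 4-line FASTQ
#'
#' Quality strings are constant placeholders (the pipeline ignores
#' quality; degraded-quality regimes are emulated through explicit
#' N-masking instead).
#'
#' @param reads character vector of reads.
#' @param path output path (gzip-compressed when it ends in \code{.gz}).
#' @param ids optional read identifiers.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}
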