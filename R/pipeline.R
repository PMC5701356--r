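#' Pipeline run configuration
#'
#' Bundles everything one multi-sample analysis needs: the ordered sample
#' files with the diagnostic flagged, the k-mer parameters, the alignment
#' scoring scheme, the clone-filter thresholds, the germline reference and
#' the MRD baseline.
#'
#' @slot samples named character vector of sample file paths, in sample
#'   order (names are the sample labels).
#' @slot diagnostic label of the diagnostic sample.
#' @slot k k-mer length.
#' @slot tau significance threshold (orders of magnitude).
#' @slot scoring a \code{\link{ScoringParams}}.
#' @slot filter a \code{\link{FilterConfig}}.
#' @slot germline path of the germline FASTA (empty to skip annotation).
#' @slot baseline diagnostic MRD anchor.
#' @slot outDir output directory (empty to skip writing).
#' @slot threads worker count for the per-sample stages.
#' @aliases RunConfig
#' @exportClass RunConfig
setClass("RunConfig",
  representation(samples = "character", diagnostic = "character",
                 k = "integer", tau = "numeric", scoring = "ScoringParams",
                 filter = "FilterConfig", germline = "character",
                 baseline = "numeric", outDir = "character",
                 threads = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@samples) < 1L) msg <- c(msg, "at least one sample is required")
  if (is.null(names(object@samples)) || any(!nzchar(names(object@samples))))
    msg <- c(msg, "samples must be named by their labels")
  if (anyDuplicated(names(object@samples))) msg <- c(msg, "sample labels must be unique")
  if (sum(names(object@samples) == object@diagnostic) != 1L)
    msg <- c(msg, "exactly one sample must match the diagnostic label")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (!(object@tau > 0)) msg <- c(msg, "tau must be > 0")
  if (!(object@baseline > 0)) msg <- c(msg, "baseline must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param samples named character vector of sample files (names = labels;
#'   unnamed vectors get labels \code{S1..Sn}).
#' @param diagnostic diagnostic sample label (default: the first).
#' @param k,tau k-mer length and significance threshold.
#' @param scoring,filter parameter objects.
#' @param germline germline FASTA path (\code{NULL} to skip annotation and
#'   Phase B).
#' @param baseline diagnostic MRD anchor (default 1, i.e. 1E+00; use e.g.
#'   0.1 for a lower-infiltration diagnosis).
#' @param outDir output directory (\code{NULL} writes nothing).
#' @param threads per-sample stage workers (results are identical to
#'   sequential execution).
#' @return A \code{RunConfig}.
#' @rdname RunConfig-class
#' @export
runConfig <- function(samples, diagnostic = NULL, k = 25L, tau = 1.0,
                      scoring = scoringParams(), filter = filterConfig(),
                      germline = NULL, baseline = 1, outDir = NULL,
                      threads = 1L) {
  samples <- unlist(samples)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("S", seq_along(samples))
  if (is.null(diagnostic)) diagnostic <- names(samples)[1L]
  missing <- samples[!file.exists(samples)]
  if (length(missing))
    stop("sample file(s) not found: ", paste(missing, collapse = ", "))
  if (!is.null(germline) && !file.exists(germline))
    stop("germline file not found: ", germline)
  new("RunConfig", samples = samples, diagnostic = diagnostic,
      k = as.integer(k), tau = as.numeric(tau), scoring = scoring,
      filter = filter, germline = if (is.null(germline)) "" else germline,
      baseline = baseline, outDir = if (is.null(outDir)) "" else outDir,
      threads = as.integer(threads))
}

.stageLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

.inStage <- function(stage, sample, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "'",
         if (nzchar(sample)) paste0(" (sample ", sample, ")") else "",
         " failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full clonotype-detection and MRD pipeline
#'
#' Chains the stages: read loading, significant k-mer selection across all
#' samples, per-sample signature collection and correction, multi-sample
#' clone accumulation, germline annotation, Phase-A and Phase-B filtering,
#' and MRD quantification of the major clone. The per-sample stages run on
#' \code{threads} workers with results identical to sequential execution.
#' The major clone for MRD tracking is taken from the Phase-A table:
#' Phase B validates germline homology for reporting but a degraded-
#' quality sample set may legitimately leave it empty while the dominant
#' clonotype remains trackable.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose log one line per stage with input/output cardinalities.
#' @return List with \code{clones} (annotated \code{\link{CloneTable}}),
#'   \code{phaseA}, \code{phaseB}, \code{major} (the tracked clone),
#'   \code{mrd} (an \code{\link{MrdSeries}}), \code{psi} (the
#'   \code{\link{SignificantKmerSet}}), and \code{files} when an output
#'   directory was configured.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  labels <- names(config@samples)
  n <- length(labels)
  diagIdx <- match(config@diagnostic, labels)

  applyFun <- if (config@threads > 1L)
    function(X, FUN) parallel::mclapply(X, FUN, mc.cores = config@threads)
  else lapply

  reads <- applyFun(seq_len(n), function(i)
    .inStage("load", labels[i],
             readSampleReads(config@samples[i], labels[i])))
  for (i in seq_len(n))
    .stageLog(verbose, "load: sample %s, %d valid read(s)", labels[i],
              length(reads[[i]]))

  psi <- .inStage("significant-kmers", "",
                  significantKmersFromReads(reads, config@k, config@tau))
  .stageLog(verbose, "significant-kmers: %d k-mer(s) at k=%d, tau=%g",
            length(psi@kmers), config@k, config@tau)

  sets <- applyFun(seq_len(n), function(i) .inStage("signatures", labels[i], {
    s <- collectSignatures(reads[[i]], psi, config@k, sampleIndex = i)
    correctSignatures(s, config@scoring)
  }))
  for (i in seq_len(n))
    .stageLog(verbose, "signatures: sample %s, %d corrected signature(s), %g empty read(s)",
              labels[i], nrow(sets[[i]]@signatures), sets[[i]]@nEmpty)

  clones <- .inStage("clones", "",
                     accumulateClones(sets, config@scoring, labels, diagIdx))
  .stageLog(verbose, "clones: %d putative clone(s)", nClones(clones))

  pa <- phaseA(clones, config@filter)
  .stageLog(verbose, "phase-A: %d -> %d clone(s) (diagnostic reads > %g)",
            nClones(clones), nClones(pa), config@filter@minDiagReads)

  # Annotation is restricted to the Phase-A survivors: Phase B only ever sees
  # them, and the sub-threshold tail (which can run to tens of thousands of
  # singleton clones in degraded-quality data) would dominate the runtime
  # without affecting any downstream result. annotateClones() remains
  # available for annotating a full table when wanted.
  pb <- if (nzchar(config@germline)) {
    db <- .inStage("germline", "", loadGermline(config@germline))
    pa <- .inStage("annotate", "", annotateClones(pa, db, config@scoring))
    .stageLog(verbose, "annotate: %d clone(s) annotated against %d segment(s)",
              nClones(pa), nrow(db@segments))
    x <- phaseB(pa, config@filter)
    .stageLog(verbose, "phase-B: %d -> %d clone(s) (V/D/J identity > %g)",
              nClones(pa), nClones(x), config@filter@minIdentity)
    x
  } else NULL

  if (nClones(clones) > 0L) {
    trackTable <- if (nClones(pa) > 0L) pa else {
      warning("no clone passed Phase A; tracking the major clone of the unfiltered table")
      clones
    }
    major <- majorClone(trackTable)
    mrd <- mrdSeries(clones, clone = major$sequence, baseline = config@baseline)
    .stageLog(verbose, "mrd: major clone at %.3g%% of diagnostic reads",
              100 * major$counts[diagIdx] / clones@sampleTotals[diagIdx])
  } else {
    warning("no clones detected (a single sample can never yield significant ",
            "k-mers: the contrast needs at least two samples)")
    major <- NULL
    mrd <- NULL
  }

  out <- list(clones = clones, phaseA = pa, phaseB = pb, major = major,
              mrd = mrd, psi = psi)

  if (nzchar(config@outDir)) {
    if (!dir.exists(config@outDir)) dir.create(config@outDir, recursive = TRUE)
    files <- c(
      report = file.path(config@outDir, "clone_report.tsv"),
      filtered = file.path(config@outDir, "clone_report_filtered.tsv"),
      mrd = file.path(config@outDir, "mrd.tsv"),
      manifest = file.path(config@outDir, "run_manifest.json"))
    writeCloneReport(clones, files[["report"]])
    writeCloneReport(if (!is.null(pb)) pb else pa, files[["filtered"]])
    if (!is.null(mrd)) writeMrdSeries(mrd, files[["mrd"]])
    else files <- files[names(files) != "mrd"]
    jsonlite::write_json(
      list(samples = as.list(config@samples), diagnostic = config@diagnostic,
           k = config@k, tau = config@tau,
           scoring = list(match = config@scoring@match,
                          mismatch = config@scoring@mismatch,
                          indel = config@scoring@indel,
                          lengthRatio = config@scoring@lengthRatio),
           filter = list(minDiagReads = config@filter@minDiagReads,
                         minIdentity = config@filter@minIdentity),
           germline = config@germline, baseline = config@baseline,
           threads = config@threads,
           n_significant_kmers = length(psi@kmers),
           n_clones = nClones(clones)),
      files[["manifest"]], auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
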