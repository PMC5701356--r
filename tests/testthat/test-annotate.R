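test_that("IMGT-dialect and plain germline headers both parse", {
  fa <- system.file("extdata", "imgt_mini_synthetic.fasta",
                    package = "CloneSight")
  db <- loadGermline(fa)
  segs <- germlineSegments(db)
  expect_equal(sum(segs$class == "V"), 3L)
  expect_equal(sum(segs$class == "D"), 2L)
  expect_equal(sum(segs$class == "J"), 2L)
  expect_true("IGHV1-2*01" %in% segs$gene)          # from a pipe header
  expect_true("IGHJ6*02" %in% segs$gene)            # from a plain header
  # IMGT alignment dots are stripped, sequences upper-cased
  expect_false(any(grepl("[^ACGTN]", segs$sequence)))

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(loadGermline(empty))

  # a file missing a whole class is a hard error naming the classes found
  vOnly <- tempfile(fileext = ".fasta")
  writeLines(c(">IGHV1-1*01", "ACGTACGT"), vOnly)
  expect_error(loadGermline(vOnly), "class")
})

test_that("exact segment copies annotate with identity 1", {
  db <- testGermline()
  segs <- germlineSegments(db)
  v <- segs[segs$class == "V", ][1, ]
  j <- segs[segs$class == "J", ][1, ]
  ann <- annotateClone(paste0(v$sequence, j$sequence), db)
  expect_equal(bestHit(ann, "V")$gene, v$gene)
  expect_equal(bestHit(ann, "V")$identity, 1)
  expect_equal(bestHit(ann, "J")$gene, j$gene)
  expect_equal(bestHit(ann, "J")$identity, 1)
  # ranking is total and deterministic
  hits <- annotationHits(ann)
  expect_false(any(duplicated(hits[, c("class", "rank")])))
  expect_error(annotateClone("", db), "non-empty")
})

test_that("identity agrees with an independent pairwise aligner", {
  # cross-check the identity definition (matches over aligned columns of the
  # local alignment) against Biostrings on gap-free and gapped cases
  db <- testGermline()
  segs <- germlineSegments(db)
  set.seed(19)
  target <- segs$sequence[segs$class == "V"][2]
  q <- strsplit(target, "")[[1]]
  pos <- sample(length(q), 12)
  q[pos] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
  query <- paste(q, collapse = "")
  al <- CloneSight:::.alignSegment(query, target, scoringParams())
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  pw <- Biostrings::pairwiseAlignment(query, target, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 3)
  expect_equal(al$score, Biostrings::score(pw))
  expect_equal(al$matches, Biostrings::nmatch(pw))
  expect_equal(al$mismatches, Biostrings::nmismatch(pw))
})

test_that("identity is invariant to flanking sequence and symmetric", {
  set.seed(29)
  core <- randomDna(50)
  a <- paste0(randomDna(20), core, randomDna(20))
  p <- scoringParams()
  alPlain <- CloneSight:::.alignSegment(core, core, p)
  alFlank <- CloneSight:::.alignSegment(core, a, p)
  expect_equal(alFlank$identity, alPlain$identity)
  expect_equal(alFlank$score, alPlain$score)
  ab <- CloneSight:::.alignSegment(core, a, p)
  ba <- CloneSight:::.alignSegment(a, core, p)
  expect_equal(ab$identity, ba$identity)
  expect_equal(ab$score, ba$score)
})

test_that("error-free rearrangements recover their V and J segments", {
  db <- testGermline()
  set.seed(37)
  segs <- germlineSegments(db)
  vg <- segs$gene[segs$class == "V"]
  dg <- segs$gene[segs$class == "D"]
  jg <- segs$gene[segs$class == "J"]
  dTop1 <- 0L
  n <- 25
  for (i in seq_len(n)) {
    r <- simulateRearrangement(db, sample(vg, 1), sample(dg, 1), sample(jg, 1),
                               vTrim = sample(0:5, 1), d5Trim = sample(0:3, 1),
                               d3Trim = sample(0:3, 1), jTrim = sample(0:5, 1),
                               n1 = sample(2:6, 1), n2 = sample(2:6, 1))
    ann <- annotateClone(r$sequence, db)
    expect_equal(bestHit(ann, "V")$gene, r$v)
    expect_equal(bestHit(ann, "J")$gene, r$j)
    if (bestHit(ann, "D")$gene == r$d) dTop1 <- dTop1 + 1L
  }
  # D is short and intrinsically ambiguous: report, don't demand 100%
  expect_gte(dTop1, 1L)
})

test_that("substitution noise leaves top V/J assignments intact", {
  db <- testGermline()
  set.seed(43)
  segs <- germlineSegments(db)
  ok <- 0L
  n <- 40
  for (i in seq_len(n)) {
    r <- simulateRearrangement(db, sample(segs$gene[segs$class == "V"], 1),
                               sample(segs$gene[segs$class == "D"], 1),
                               sample(segs$gene[segs$class == "J"], 1))
    noisy <- as.character(CloneSight:::cpp_mutate_reads(r$sequence, 0.02, 0))
    ann <- annotateClone(noisy, db)
    if (bestHit(ann, "V")$gene == r$v && bestHit(ann, "J")$gene == r$j)
      ok <- ok + 1L
  }
  expect_gte(ok / n, 0.95)
})

test_that("N-masking the D region does not disturb V and J assignments", {
  db <- testGermline()
  set.seed(47)
  segs <- germlineSegments(db)
  for (i in 1:10) {
    r <- simulateRearrangement(db, sample(segs$gene[segs$class == "V"], 1),
                               sample(segs$gene[segs$class == "D"], 1),
                               sample(segs$gene[segs$class == "J"], 1),
                               vTrim = 2, d5Trim = 1, d3Trim = 1, jTrim = 2,
                               n1 = 5, n2 = 5)
    clean <- annotateClone(r$sequence, db)
    # mask 30% of the D-region bases with N
    vLen <- nchar(segs$sequence[segs$gene == r$v]) - r$vTrim
    dLen <- nchar(segs$sequence[segs$gene == r$d]) - r$d5Trim - r$d3Trim
    dStart <- vLen + r$n1 + 1L
    s <- strsplit(r$sequence, "")[[1]]
    dPos <- dStart:(dStart + dLen - 1L)
    s[sample(dPos, max(1, round(0.3 * dLen)))] <- "N"
    masked <- paste(s, collapse = "")
    mAnn <- annotateClone(masked, db)
    expect_equal(bestHit(mAnn, "V")$gene, bestHit(clean, "V")$gene)
    expect_equal(bestHit(mAnn, "J")$gene, bestHit(clean, "J")$gene)
  }
})

test_that("annotateClones fills best hits per clone and enables phase B", {
  db <- testGermline()
  segs <- germlineSegments(db)
  v <- segs[segs$class == "V", ][2, ]
  j <- segs[segs$class == "J", ][2, ]
  tab <- makeCloneTable(rbind(c(300, 5), c(200, 1)),
                        sequences = c(paste0(v$sequence, j$sequence),
                                      randomDna(80)))
  expect_false(isAnnotated(tab))
  expect_error(phaseB(tab), "annotate")
  ann <- annotateClones(tab, db)
  expect_true(isAnnotated(ann))
  expect_equal(annotation(ann)$v_gene[1], v$gene)
  expect_equal(annotation(ann)$v_identity[1], 1)
})
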