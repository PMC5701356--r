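test_that("the toy germline is deterministic and well-formed", {
  a <- makeToyGermline(1)
  b <- makeToyGermline(1)
  expect_identical(a, b)
  expect_false(identical(a, makeToyGermline(2)))

  tf <- tempfile(fileext = ".fasta")
  writeLines(a, tf)
  db <- loadGermline(tf)
  segs <- germlineSegments(db)
  expect_gte(sum(segs$class == "V"), 5L)
  expect_gte(sum(segs$class == "D"), 4L)
  expect_gte(sum(segs$class == "J"), 4L)
  vLens <- nchar(segs$sequence[segs$class == "V"])
  expect_true(all(vLens >= 240 & vLens <= 260))

  # pairwise V identities below 0.9 so assignments are unambiguous
  v <- segs$sequence[segs$class == "V"]
  p <- scoringParams()
  for (i in seq_along(v)[-1]) for (j in seq_len(i - 1)) {
    al <- CloneSight:::.alignSegment(v[i], v[j], p)
    expect_lt(al$matches / min(nchar(v[i]), nchar(v[j])), 0.9)
  }
})

test_that("rearrangements concatenate trimmed segments around inserts", {
  db <- testGermline()
  segs <- germlineSegments(db)
  v <- segs[segs$class == "V", ][1, ]
  d <- segs[segs$class == "D", ][1, ]
  j <- segs[segs$class == "J", ][1, ]
  r0 <- simulateRearrangement(db, v$gene, d$gene, j$gene, vTrim = 0,
                              d5Trim = 0, d3Trim = 0, jTrim = 0, n1 = 0, n2 = 0)
  expect_equal(r0$sequence, paste0(v$sequence, d$sequence, j$sequence))

  set.seed(5); ra <- simulateRearrangement(db, v$gene, d$gene, j$gene)
  set.seed(5); rb <- simulateRearrangement(db, v$gene, d$gene, j$gene)
  expect_identical(ra$sequence, rb$sequence)

  expect_error(simulateRearrangement(db, v$gene, d$gene, j$gene,
                                     vTrim = nchar(v$sequence)), "V trim")
  expect_error(simulateRearrangement(db, v$gene, d$gene, j$gene,
                                     d5Trim = 20, d3Trim = 20), "D trims")

  # round trip: the top V/J annotation recovers the chosen segments
  ann <- annotateClone(ra$sequence, db)
  expect_equal(bestHit(ann, "V")$gene, v$gene)
  expect_equal(bestHit(ann, "J")$gene, j$gene)
})

test_that("sample simulation respects fractions and error rates", {
  db <- testGermline()
  set.seed(7)
  clone <- simulateRearrangement(db, "IGHV1-1*01", "IGHD1-1*01", "IGHJ1*01")

  # pure single clone, no error: all reads identical
  pure <- simulateSample(db, clone$sequence, 1.0, 50, subRate = 0, nRate = 0)
  expect_true(all(pure$reads == clone$sequence))

  # spiked fraction within 3 sigma of binomial expectation
  s <- simulateSample(db, clone$sequence, 0.1, 1e4, subRate = 0, nRate = 0)
  expect_lt(abs(s$cloneCounts[1] - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
  expect_equal(sum(s$assignment == 1), s$cloneCounts[1])

  # N-masking rate close to nominal over ~1e5 bases
  sN <- simulateSample(db, clone$sequence, 0.5, 300, subRate = 0, nRate = 0.3)
  basesN <- sum(nchar(gsub("[^N]", "", sN$reads)))
  expect_lt(abs(basesN / sum(nchar(sN$reads)) - 0.3), 0.02)

  expect_error(simulateSample(db, clone$sequence, 1.2, 10), "sum to <= 1")
})

test_that("run-structured N-masking keeps the marginal rate and forms runs", {
  db <- testGermline()
  set.seed(9)
  clone <- simulateRearrangement(db, "IGHV1-1*01", "IGHD1-1*01", "IGHJ1*01")
  s <- simulateSample(db, clone$sequence, 0.5, 400, subRate = 0,
                      nRate = 0.3, nRunLength = 30)
  frac <- sum(nchar(gsub("[^N]", "", s$reads))) / sum(nchar(s$reads))
  # a small edge deficit (< half a run length per read) is expected
  expect_lt(abs(frac - 0.3), 0.03)
  # masking is clumped: far fewer N runs than masked bases
  runs <- unlist(lapply(gregexpr("N+", s$reads), function(g)
    if (g[1] == -1) integer(0) else attr(g, "match.length")))
  expect_gt(mean(runs), 10)
})

test_that("dilution series are deterministic under seed with exact read counts", {
  d1 <- tempfile(); d2 <- tempfile()
  a <- dilutionSeries(fractions = c(0.9, 0.1), nReads = 400, seed = 99, dir = d1)
  b <- dilutionSeries(fractions = c(0.9, 0.1), nReads = 400, seed = 99, dir = d2)
  for (i in 1:2) {
    expect_identical(a$samples[[i]]$reads, b$samples[[i]]$reads)
    expect_identical(readLines(a$files[i]), readLines(b$files[i]))
    expect_equal(length(a$samples[[i]]$reads), 400L)
  }
  expect_identical(readLines(a$germlineFile), readLines(b$germlineFile))
  # truth manifest carries the spiked clone and per-sample fractions
  truth <- jsonlite::read_json(a$manifest, simplifyVector = TRUE)
  expect_equal(truth$fractions, c(0.9, 0.1))
  expect_equal(truth$clone$sequence, a$clone$sequence)
  # FASTQ round trip through the reader
  reads <- readSampleReads(a$files[[1]])
  expect_identical(reads, a$samples[[1]]$reads)
})

test_that("polyclonal background reads are essentially unique junctions", {
  db <- testGermline()
  set.seed(11)
  bg <- CloneSight:::.randomRearrangements(db, 500)
  expect_gte(length(unique(bg)), 495L)
})
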