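test_that("signatures are the union of covered intervals, in read order", {
  # Covered positions of {CCC, CCG, CGT} in ATCCCGTC are 3..7: the signature
  # is "CCCGT", not the shorter "CCGT" occasionally quoted for this example
  # (which cannot be reconciled with the k-mer positions).
  expect_equal(buildSignature("ATCCCGTC", c("CCC", "CCG", "CGT"), 3), "CCCGT")
  expect_equal(buildSignature("ATCCCGTC", character(0), 3), "")
  expect_equal(buildSignature("AAAATTTTGGGG", c("AAAA", "GGGG"), 4),
               "AAAAGGGG")

  set.seed(5)
  for (i in 1:20) {
    read <- randomDna(sample(8:40, 1), c("A", "C", "G", "T", "N"))
    k <- sample(3:6, 1)
    all <- extractKmers(read, k)$kmer
    psi <- unique(sample(all, min(length(all), sample(1:5, 1))))
    expect_equal(buildSignature(read, psi, k), oracleSignature(read, psi, k))
  }
})

test_that("collection pools identical signatures and tracks exemplars", {
  reads <- rep("ATCCCGTC", 10)
  s <- collectSignatures(reads, c("CCC", "CCG", "CGT"), 3, sampleIndex = 2L)
  df <- signatures(s)
  expect_equal(nrow(df), 1L)
  expect_equal(df$frequency, 10)
  expect_equal(df$sequence, "CCCGT")
  expect_equal(df$exemplar, "ATCCCGTC")
  expect_equal(sampleIndex(s), 2L)
  expect_equal(s@nEmpty, 0)

  # disjoint significant k-mers give distinct frequency-1 signatures
  s2 <- collectSignatures(c("AAAATCGC", "GGGGTAAC", "TTTTTTTT"),
                          c("AAAA", "GGGG"), 4)
  expect_equal(sort(signatures(s2)$sequence), c("AAAA", "GGGG"))
  expect_equal(signatures(s2)$frequency, c(1, 1))
  expect_equal(s2@nEmpty, 1)

  # agreement with the per-read surface on random input
  set.seed(31)
  reads <- vapply(rep(30, 50), randomDna, character(1))
  psi <- unique(unlist(lapply(reads[1:5], function(r) extractKmers(r, 6)$kmer)))
  s3 <- collectSignatures(reads, psi, 6)
  perRead <- vapply(reads, buildSignature, character(1), psi = psi, k = 6,
                    USE.NAMES = FALSE)
  expect_equal(sum(signatures(s3)$frequency), sum(nzchar(perRead)))
  expect_equal(s3@nEmpty, sum(!nzchar(perRead)))
  expect_equal(sort(signatures(s3)$sequence), sort(unique(perRead[nzchar(perRead)])))
})

test_that("alignment scores match an independent DP oracle", {
  expect_equal(swScore("ACGT", "ACGT"), 8)
  expect_equal(swScore("ACGT", "TTTT"), 2)
  expect_error(swScore("", "ACGT"), "non-empty")

  set.seed(17)
  for (i in 1:200) {
    a <- randomDna(sample(1:12, 1), c("A", "C", "G", "T", "N"))
    b <- randomDna(sample(1:12, 1), c("A", "C", "G", "T", "N"))
    p <- scoringParams(match = sample(1:3, 1), mismatch = sample(0:3, 1),
                       indel = sample(0:3, 1))
    got <- swScore(a, b, p)
    expect_identical(got, as.integer(oracleSw(a, b, p@match, p@mismatch, p@indel)))
    expect_identical(got, swScore(b, a, p))     # symmetry
  }
})

test_that("N never scores as a match, even against another N", {
  expect_equal(swScore("NNNN", "NNNN"), 0)
  expect_equal(swScore("ACNGT", "ACNGT"), 6)    # the N column costs a mismatch
})

test_that("the similarity threshold reproduces the two-branch formula", {
  # hand-computed with defaults M = MM = 2, IN = 3 (ELSE coefficient 0.92)
  cases <- list(
    list(10, 6, 20), list(10, 10, 9.2), list(10, 7, 9.2), list(1, 1, 0.92),
    list(100, 60, 200), list(100, 70, 92), list(100, 69, 200),
    list(50, 40, 46), list(50, 34, 100), list(50, 35, 46),
    list(20, 20, 18.4), list(20, 13, 40), list(20, 14, 18.4),
    list(7, 5, 6.44), list(7, 4, 14), list(200, 200, 184),
    list(33, 23, 66), list(33, 24, 30.36), list(13, 9, 26), list(13, 10, 11.96))
  for (cs in cases) {
    expect_equal(similarityThreshold(cs[[1]], cs[[2]]), cs[[3]], tolerance = 1e-12)
    expect_equal(similarityThreshold(cs[[2]], cs[[1]]), cs[[3]], tolerance = 1e-12)
  }
  set.seed(3)
  for (i in 1:50) {
    la <- sample(1:300, 1); lb <- sample(1:300, 1)
    M <- sample(1:3, 1); MM <- sample(0:3, 1); IN <- sample(0:4, 1)
    p <- scoringParams(M, MM, IN)
    expect_equal(similarityThreshold(la, lb, p), oracleThreshold(la, lb, M, MM, IN))
  }
})

test_that("pairs below the 70% length ratio can never be similar", {
  expect_false(areSimilar(strrep("A", 100), strrep("A", 60)))
  set.seed(23)
  for (i in 1:100) {
    lmax <- sample(10:80, 1)
    lmin <- sample(1:max(1, floor(lmax * 0.7 - 1e-9)), 1)
    if (lmax * 0.7 <= lmin) next
    a <- randomDna(lmax)
    b <- substr(a, 1, lmin)   # worst case: perfect containment
    expect_false(areSimilar(a, b))
  }
  # at equal lengths identical strings are always similar
  expect_true(areSimilar("ACGTACGTAC", "ACGTACGTAC"))
  # one mismatch at length 20: score 36 > threshold 18.4
  a <- strrep("ACGT", 5)
  b <- paste0(substr(a, 1, 9), "T", substr(a, 11, 20))
  expect_true(areSimilar(a, b))
})

test_that("correction absorbs the lower-frequency member and conserves totals", {
  s <- makeSignatureSet(c("ACGTACGTACGTACGTACGT", "ACGTACGTACTTACGTACGT"),
                        c(100, 3))
  out <- correctSignatures(s)
  df <- signatures(out)
  expect_equal(nrow(df), 1L)
  expect_equal(df$frequency, 103)
  expect_equal(df$sequence, "ACGTACGTACGTACGTACGT")  # survivor = higher freq

  # pairwise-dissimilar sets are a fixed point
  dis <- makeSignatureSet(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
                          c(5, 4, 3))
  expect_equal(signatures(correctSignatures(dis)), signatures(dis))
})

test_that("correction is idempotent, conservative, and respects the 70% rule", {
  set.seed(71)
  base <- randomDna(60)
  variants <- vapply(1:15, function(i) {
    s <- strsplit(base, "")[[1]]
    pos <- sample(60, sample(1:3, 1))
    s[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  short <- vapply(1:5, function(i) randomDna(30), character(1))  # < 0.7 * 60
  seqs <- unique(c(base, variants, short))
  freq <- sample(1:50, length(seqs), replace = TRUE)
  s <- makeSignatureSet(seqs, freq)
  out <- correctSignatures(s)
  expect_equal(sum(signatures(out)$frequency), sum(freq))
  # fixed point
  out2 <- correctSignatures(out)
  expect_equal(signatures(out2), signatures(out))
  # nothing short merged into the long cluster (70% rule)
  expect_true(all(short %in% signatures(out)$sequence))
  # no remaining similar pair
  df <- signatures(out)
  if (nrow(df) > 1) {
    for (i in seq_len(nrow(df) - 1)) for (j in (i + 1):nrow(df))
      expect_false(areSimilar(df$sequence[i], df$sequence[j]))
  }
})

test_that("a noisy clone collapses to one signature carrying all its reads", {
  set.seed(77)
  clone <- randomDna(80)
  reads <- vapply(1:500, function(i) {
    s <- strsplit(clone, "")[[1]]
    err <- runif(80) < 0.01
    s[err] <- sample(c("A", "C", "G", "T"), sum(err), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  psi <- extractKmers(clone, 12)$kmer
  s <- correctSignatures(collectSignatures(reads, psi, 12))
  df <- signatures(s)
  expect_equal(sum(df$frequency) + s@nEmpty, 500)
  expect_gte(df$frequency[1], 450)   # dominant signature absorbs the variants
})

test_that("signature sets serialize to the TSV dialect", {
  s <- makeSignatureSet(c("ACGT", "GGCC"), c(7, 2),
                        exemplars = c("AACGTT", "GGGCCC"))
  tf <- tempfile(fileext = ".tsv")
  writeSignatureSet(s, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "#sequence\tfrequency\texemplar")
  expect_equal(lines[2], "ACGT\t7\tAACGTT")
  expect_equal(length(lines), 3L)
})
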