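test_that("sliding-window extraction enumerates every k-mer in read order", {
  km <- extractKmers("ATCCCGTC", 3)
  expect_equal(km$kmer, c("ATC", "TCC", "CCC", "CCG", "CGT", "GTC"))
  expect_equal(km$start, 1:6)

  expect_equal(nrow(extractKmers("AC", 3)), 0L)
  expect_equal(extractKmers("AAAA", 2),
               data.frame(kmer = c("AA", "AA", "AA"), start = 1:3))
  expect_error(extractKmers("ACGT", 0), "positive")
  expect_error(extractKmers("ACGT", -2), "positive")
})

test_that("per-sample counting uses occurrence (not read-presence) semantics", {
  expect_equal(countSampleKmers("ATCCCGTC", 3),
               c(ATC = 1L, CCC = 1L, CCG = 1L, CGT = 1L, GTC = 1L, TCC = 1L))
  expect_equal(length(countSampleKmers(character(0), 3)), 0L)
  expect_equal(countSampleKmers(c("AAAA", "AAA"), 3), c(AAA = 3L))
  # k-mers containing N are counted verbatim as a fifth literal
  withN <- countSampleKmers("ANA", 2)
  expect_equal(names(withN), c("AN", "NA"))
  expect_equal(unname(withN), c(1L, 1L))
})

test_that("counting conserves the sliding-window total per sample", {
  set.seed(42)
  for (k in c(3, 12, 25, 45)) {   # 45 exercises the unpacked fallback
    reads <- vapply(sample(10:60, 30, replace = TRUE), randomDna, character(1))
    counts <- countSampleKmers(reads, k)
    expect_equal(sum(counts), sum(pmax(nchar(reads) - k + 1, 0)))
  }
})

test_that("merging encodes absences as zero and preserves per-sample counts", {
  m <- mergeCounts(list(c(ATC = 3L), setNames(integer(0), character(0))))
  expect_equal(unname(kmerCounts(m)["ATC", ]), c(3L, 0L))

  one <- mergeCounts(list(c(AAA = 2L, TTT = 5L)))
  expect_equal(kmerCounts(one)[, 1], c(AAA = 2L, TTT = 5L))

  two <- mergeCounts(list(countSampleKmers("ATCCCGTC", 3),
                          countSampleKmers("ATCATC", 3)))
  expect_equal(kmerCounts(two)["ATC", ], c(S1 = 1L, S2 = 2L))

  expect_error(mergeCounts(list(c(AT = 1L), c(ATC = 1L))), "different k")
})

test_that("significance matches the printed three-case rule", {
  expect_true(isSignificant(c(1000, 2000, 25000), 1))
  expect_false(isSignificant(c(0, 0, 0), 1))
  expect_false(isSignificant(c(50, 50), 1))
  expect_true(isSignificant(c(0, 10), 1))
  expect_false(isSignificant(c(0, 9), 1))
  expect_false(isSignificant(1000, 1))          # n = 1: no pair exists
  expect_error(isSignificant(c(1, 2), 0), "positive")
  expect_error(isSignificant(c(1, 2), -1), "positive")
})

test_that("significant-kmer selection equals brute-force pair enumeration", {
  set.seed(7)
  for (rep in 1:3) {
    n <- sample(2:5, 1)
    nk <- 120
    kms <- unique(vapply(seq_len(nk), function(i) randomDna(6), character(1)))
    counts <- matrix(rpois(length(kms) * n, lambda = 8) *
                       rbinom(length(kms) * n, 1, 0.8),
                     nrow = length(kms),
                     dimnames = list(kms, paste0("S", seq_len(n))))
    counts[sample(length(counts), 25)] <- sample(c(0, 500, 4000), 25, TRUE)
    tab <- new("KmerTable", k = 6L, counts = counts)
    for (tau in c(0.5, 1, 2)) {
      got <- kmers(significantKmers(tab, tau))
      want <- sort(rownames(counts)[
        vapply(seq_len(nrow(counts)),
               function(i) oracleSignificant(counts[i, ], tau), logical(1))])
      expect_equal(got, want)
    }
  }
})

test_that("selection is monotone in tau and invariant to sample permutation", {
  set.seed(13)
  reads <- list(
    vapply(rep(30, 40), randomDna, character(1)),
    vapply(rep(30, 40), randomDna, character(1)),
    vapply(rep(30, 40), randomDna, character(1)))
  reads[[1]] <- c(reads[[1]], rep(randomDna(30), 50))  # sample-1-specific k-mers
  tab <- mergeCounts(lapply(reads, countSampleKmers, k = 8))
  taus <- c(0.3, 0.7, 1, 1.5)
  sets <- lapply(taus, function(t) kmers(significantKmers(tab, t)))
  for (i in seq_along(taus)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))

  perm <- c(3, 1, 2)
  tabP <- mergeCounts(lapply(reads[perm], countSampleKmers, k = 8))
  expect_equal(unname(kmerCounts(tabP)), unname(kmerCounts(tab)[, perm]))
  expect_equal(kmers(significantKmers(tabP, 1)), kmers(significantKmers(tab, 1)))
})

test_that("the streaming selector agrees with the table-based path", {
  set.seed(99)
  reads <- lapply(1:3, function(i)
    c(vapply(rep(40, 30), randomDna, character(1)),
      rep(randomDna(40), c(120, 12, 1)[i])))
  for (tau in c(0.5, 1)) {
    viaTable <- kmers(significantKmers(
      mergeCounts(lapply(reads, countSampleKmers, k = 10)), tau))
    viaStream <- kmers(significantKmersFromReads(reads, 10, tau))
    expect_equal(viaStream, viaTable)
  }
})

test_that("k-mer tables round-trip through the TSV dialect", {
  tab <- mergeCounts(list(countSampleKmers("ATCCCGTC", 3),
                          countSampleKmers("ATCATCGG", 3)),
                     labels = c("diag", "fu1"))
  tf <- tempfile(fileext = ".tsv")
  writeKmerTable(tab, tf)
  expect_true(startsWith(readLines(tf, n = 1), "#"))
  back <- readKmerTable(tf)
  expect_equal(kmerCounts(back), kmerCounts(tab))
  expect_equal(back@k, tab@k)
})

test_that("invalid bases are rejected with an informative error", {
  expect_error(countSampleKmers("ACGU", 2), "outside")
  expect_error(significantKmersFromReads(list("ACGT", "ACXT"), 2, 1), "outside")
})
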