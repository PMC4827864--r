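params <- alnParams()

test_that("self-alignment scores the matrix diagonal at 100% identity", {
  aln <- globalAlign("ACDEFGHIKL", "ACDEFGHIKL")
  m <- getSubMatrix("BLOSUM62")
  expect_equal(alnScore(aln),
               sum(diag(m)[match(strsplit("ACDEFGHIKL", "")[[1]],
                                 rownames(m))]))
  expect_equal(percentIdentity(aln), 100)
  expect_equal(percentSimilarity(aln), 100)
})

test_that("a conservative substitution lowers identity but not similarity", {
  # L -> I scores +2 in BLOSUM62: a similarity but not an identity
  aln <- globalAlign("ACLE", "ACIE")
  expect_equal(percentIdentity(aln), 75)
  expect_equal(percentSimilarity(aln), 100)
})

test_that("global scores match exhaustive enumeration on short peptides", {
  set.seed(11)
  m <- getSubMatrix("BLOSUM62")
  for (i in 1:12) {
    a <- randomAA(sample(4:7, 1))
    b <- randomAA(sample(4:7, 1))
    expect_equal(alnScore(globalAlign(a, b, params)),
                 bruteGlobalScore(a, b, m, 8, 2),
                 info = paste(a, b))
  }
})

test_that("local scores match exhaustive substring enumeration", {
  set.seed(12)
  m <- getSubMatrix("BLOSUM62")
  for (i in 1:6) {
    a <- randomAA(5)
    b <- randomAA(5)
    expect_equal(alnScore(localAlign(a, b, params)),
                 bruteLocalScore(a, b, m, 8, 2),
                 info = paste(a, b))
  }
})

test_that("scores agree with an independent alignment implementation", {
  # Biostrings uses gapOpening + gapExtension * L, so its opening penalty
  # is ours minus one extension
  set.seed(13)
  for (i in 1:10) {
    a <- randomAA(sample(30:90, 1))
    b <- randomAA(sample(30:90, 1))
    expect_equal(alnScore(globalAlign(a, b, params)),
                 Biostrings::pairwiseAlignment(
                   Biostrings::AAString(a), Biostrings::AAString(b),
                   substitutionMatrix = "BLOSUM62", gapOpening = 6,
                   gapExtension = 2, type = "global", scoreOnly = TRUE))
    expect_equal(alnScore(localAlign(a, b, params)),
                 max(0, Biostrings::pairwiseAlignment(
                   Biostrings::AAString(a), Biostrings::AAString(b),
                   substitutionMatrix = "BLOSUM62", gapOpening = 6,
                   gapExtension = 2, type = "local", scoreOnly = TRUE)))
  }
})

test_that("global score is symmetric", {
  set.seed(14)
  for (i in 1:5) {
    a <- randomAA(40); b <- randomAA(55)
    expect_equal(alnScore(globalAlign(a, b)), alnScore(globalAlign(b, a)))
  }
})

test_that("mutually negative homopolymers give an empty local alignment", {
  aln <- localAlign(strrep("P", 20), strrep("W", 20))
  expect_equal(alnScore(aln), 0)
  expect_identical(aln@spanA, c(0L, -1L))
  expect_identical(nchar(aln@alignedA), 0L)
})

test_that("a shared 60-mer embedded in random flanks is recovered locally", {
  set.seed(15)
  core <- randomAA(60)
  a <- paste0(randomAA(40), core, randomAA(30))
  b <- paste0(randomAA(25), core, randomAA(45))
  aln <- localAlign(a, b)
  expect_true(aln@spanA[1] <= 41 && aln@spanA[2] >= 100)
  expect_true(aln@spanB[1] <= 26 && aln@spanB[2] >= 85)
  # the local alignment scores at least the core-vs-core self-match
  expect_gte(alnScore(aln), alnScore(globalAlign(core, core)))
})

test_that("empty sequences are rejected", {
  expect_error(globalAlign("", "ACD"), "non-empty")
  expect_error(localAlign("ACD", ""), "non-empty")
})

test_that("comparable-segment trimming matches the exhaustive scan", {
  rule <- segmentRule(minLength = 10L)
  set.seed(16)
  for (i in 1:6) {
    a <- randomAA(sample(40:70, 1))
    b <- randomAA(sample(40:70, 1))
    aln <- globalAlign(a, b)
    seg <- extractComparableSegment(aln, rule)
    oracle <- bruteComparableSegment(aln@alignedA, aln@alignedB, 10L)
    if (is.null(seg)) {
      expect_true(is.infinite(oracle$value) || is.null(oracle$columns))
    } else {
      expect_equal(seg$value, oracle$value)
      # returned segments are contiguous substrings of the inputs
      expect_identical(seg$segA,
                       substr(a, seg$spanA[1], seg$spanA[2]))
      expect_identical(seg$segB,
                       substr(b, seg$spanB[1], seg$spanB[2]))
    }
  }
})

test_that("all-gap alignment ends are trimmed; short alignments yield NULL", {
  # force end overhangs with end-gap-free parameters
  a <- paste0(strrep("G", 15), strrep("ACDEFGHIKLMNPQRSTVWY", 2))
  b <- strrep("ACDEFGHIKLMNPQRSTVWY", 2)
  aln <- globalAlign(a, b, alnParams(endGapsFree = TRUE))
  seg <- extractComparableSegment(aln, segmentRule(minLength = 20L))
  expect_false(is.null(seg))
  expect_false(grepl("-", substr(seg$segA, 1, 1)))
  # two 59-mers can never satisfy the 60-residue rule
  expect_null(extractComparableSegment(globalAlign(randomAA(59),
                                                   randomAA(59)),
                                       segmentRule(minLength = 60L)))
})

test_that("the text report marks identities and similarities", {
  aln <- globalAlign("ACLEFGHIKL", "ACIEFGHIKL", idA = "x", idB = "y")
  rep <- writeAlignmentReport(aln, file = withr::local_tempfile())
  expect_true(any(grepl("\\|", rep)))   # identity bars
  expect_true(any(grepl(":", rep)))     # the L/I similarity colon
  expect_true(any(grepl("identity 90.0%", rep)))
})
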