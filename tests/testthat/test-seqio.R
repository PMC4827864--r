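test_that("FASTA reading parses, normalizes and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">1.B.4.2.4 some porin", "acdefGHIKL", "MNPQR",
               ">Req1", "WYVTS-"), f)
  x <- readFastaSet(f)
  expect_length(x, 2L)
  expect_identical(names(x), c("1.B.4.2.4", "Req1"))
  expect_identical(as.character(x[[1]]), "ACDEFGHIKLMNPQR")  # upper-cased
  expect_identical(as.character(x[[2]]), "WYVTS")            # gap stripped
  expect_identical(S4Vectors::mcols(x)$family, c("1.B.4", NA))

  # round trip preserves ids and sequences exactly
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFastaSet(x, f2)
  y <- readFastaSet(f2)
  expect_identical(chr(y), chr(x))

  # errors: duplicate id, empty file, headerless file
  writeLines(c(">a", "ACDE", ">a", "GHIK"), f)
  expect_error(readFastaSet(f), "duplicate")
  writeLines(character(0), f)
  expect_error(readFastaSet(f), "empty")
  writeLines(c("ACDE", ">a", "GHIK"), f)
  expect_error(readFastaSet(f), "header")
})

test_that("TC identifiers decompose and non-TC ids return NA", {
  p <- parseTcId(c("1.B.4.2.4", "1.B.1.1.1", "Req1", "1.B.43.1.1"))
  expect_equal(p$family, c(4L, 1L, NA, 43L))
  expect_equal(p$subfamily, c(2L, 1L, NA, 1L))
  expect_equal(p$protein, c(4L, 1L, NA, 1L))
  expect_equal(tcFamily(c("1.B.58.1.2", "Nbr4")), c("1.B.58", NA))
})

test_that("redundancy reduction retains one representative per cluster", {
  s <- randomAA(80)
  mut <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(AA20, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  set.seed(42)
  # two near-duplicates of s, plus two unrelated sequences
  set <- makeSeqSet(c(a = s, b = mut(s, 4), c = randomAA(80),
                      d = randomAA(80)))
  red <- reduceRedundancy(set, cutoff = 0.85)
  expect_true(length(red) < 4L)
  cl <- S4Vectors::metadata(red)$clusters
  # every input is accounted for exactly once
  expect_setequal(cl$member_id, c("a", "b", "c", "d"))
  # no retained pair above the cutoff; every removed member is above the
  # cutoff against its representative (exhaustive check)
  reps <- names(red)
  for (i in seq_along(reps)) for (j in seq_len(i - 1L))
    expect_lte(pairIdentity(chr(red)[i], chr(red)[j]), 0.85)
  removed <- setdiff(cl$member_id, reps)
  for (m in removed) {
    r <- cl$representative_id[cl$member_id == m]
    expect_gt(pairIdentity(chr(set)[r], chr(set)[m]), 0.85)
  }
})

test_that("redundancy reduction is idempotent and monotone in the cutoff", {
  set.seed(7)
  seqs <- vapply(1:8, function(i) randomAA(60), character(1))
  base <- randomAA(60)
  # add a clutch of close variants of one base sequence
  vars <- vapply(1:4, function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[sample(60, 3)] <- sample(AA20, 3, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  set <- makeSeqSet(setNames(c(seqs, base, vars),
                             paste0("s", 1:13)))
  r1 <- reduceRedundancy(set, 0.85)
  r2 <- reduceRedundancy(r1, 0.85)
  expect_identical(chr(r1), chr(r2))
  nRetained <- vapply(c(0.95, 0.85, 0.60, 0.30), function(co)
    length(reduceRedundancy(set, co)), integer(1))
  expect_true(all(diff(nRetained) <= 0L))
})
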