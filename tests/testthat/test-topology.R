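test_that("a poly-I profile sits at the isoleucine hydropathy value", {
  pr <- avehasProfile(makeSeqSet(c(a = strrep("I", 30))), window = 9)
  # interior columns: full windows of I at Kyte-Doolittle 4.5
  expect_equal(pr$hydropathy[10:20], rep(4.5, 11))
  expect_equal(pr$similarity, rep(1, 30))
})

test_that("alternating I/S maximizes the 180-degree hydrophobic moment", {
  s <- paste(rep(c("I", "S"), 10), collapse = "")
  pr180 <- avehasProfile(makeSeqSet(c(a = s)), window = 9, angle = 180)
  pr100 <- avehasProfile(makeSeqSet(c(a = s)), window = 9, angle = 100)
  mid <- 8:13
  # closed form for a perfect period-2 sequence at delta = pi: every term
  # contributes |h| coherently, mu = mean(|h - hbar| ... ) reduces to
  # (h_I - h_S) / 2 = (4.5 + 0.8) / 2 = 2.65
  expect_equal(mean(pr180$amphipathicity[mid]), 2.65, tolerance = 0.01)
  expect_lt(mean(pr100$amphipathicity[mid]),
            mean(pr180$amphipathicity[mid]) / 2)
})

test_that("profiles are invariant to row order and reject ragged input", {
  sf <- evolveFamily(makeAncestor(barrelSpec(6L), seed = 3),
                     familySpec(4L, targetIdentity = 0.6, indelRate = 0,
                                seed = 1))
  aln <- chr(sf)   # no indels, so members align column-for-column
  p1 <- avehasProfile(aln)
  p2 <- avehasProfile(rev(aln))
  expect_equal(p1$hydropathy, p2$hydropathy)
  expect_equal(p1$similarity, p2$similarity)
  expect_error(avehasProfile(c(a = "ACDE", b = "ACD")), "ragged")
})

test_that("similarity peaks co-locate with planted strands", {
  skip_if(Sys.which("mafft") == "")
  anc <- makeAncestor(barrelSpec(8L), seed = 11)
  fam <- evolveFamily(anc, familySpec(6L, targetIdentity = 0.5, seed = 2))
  aln <- mafftAlign(fam)
  pr <- avehasProfile(aln)
  # map ancestor strand columns through the first member (no indels in
  # strands, so member coordinates equal ancestor coordinates there)
  g <- strsplit(chr(aln)[[1]], "")[[1]]
  colOf <- which(g != "-")
  truth <- S4Vectors::metadata(fam)$strandRanges[[1]]
  inStrand <- rep(FALSE, length(g))
  for (k in seq_along(truth)) {
    span <- IRanges::start(truth)[k]:IRanges::end(truth)[k]
    inStrand[colOf[span]] <- TRUE
  }
  expect_gt(mean(pr$similarity[inStrand], na.rm = TRUE),
            mean(pr$similarity[!inStrand & pr$occupancy > 0.5],
                 na.rm = TRUE))
})

test_that("loop-only sequences yield no strands; barrels yield about 2n", {
  expect_equal(nStrands(predictBetaTms(strrep("S", 120))), 0L)
  anc <- makeAncestor(barrelSpec(8L), seed = 21)
  tp <- predictBetaTms(anc$seq)
  expect_lte(abs(nStrands(tp) - 16L), 3L)
  # every planted strand overlapped by some call
  called <- strandRanges(tp)
  truth <- strandRanges(anc$topology)
  hits <- IRanges::countOverlaps(truth, called)
  expect_gte(mean(hits > 0), 0.8)
})

test_that("strand calls mirror under sequence reversal", {
  anc <- makeAncestor(barrelSpec(6L), seed = 22)
  s <- anc$seq
  fwd <- strandRanges(predictBetaTms(s))
  rev <- strandRanges(predictBetaTms(
    paste(rev(strsplit(s, "")[[1]]), collapse = "")))
  n <- nchar(s)
  mirrored <- IRanges::IRanges(start = n - IRanges::end(rev) + 1L,
                               end = n - IRanges::start(rev) + 1L)
  mirrored <- mirrored[order(IRanges::start(mirrored))]
  expect_equal(IRanges::start(fwd), IRanges::start(mirrored))
  expect_equal(IRanges::end(fwd), IRanges::end(mirrored))
})

test_that("family strand-count histograms capture mixtures and modes", {
  f8 <- evolveFamily(makeAncestor(barrelSpec(4L), seed = 31),
                     familySpec(4L, targetIdentity = 0.7, seed = 1),
                     prefix = "b8")
  f16 <- evolveFamily(makeAncestor(barrelSpec(8L), seed = 32),
                      familySpec(4L, targetIdentity = 0.7, seed = 2),
                      prefix = "b16")
  ct <- countTmsByFamily(list(small = f8, large = f16))
  expect_lte(abs(ct$summary$modal_strands[ct$summary$family == "small"] - 8L),
             2L)
  expect_lte(abs(ct$summary$modal_strands[ct$summary$family == "large"] - 16L),
             2L)
  mixed <- makeSeqSet(c(chr(f8), chr(f16)))
  ctm <- countTmsByFamily(list(mix = mixed))
  expect_gte(length(ctm$histograms$mix), 2L)   # bimodal-ish histogram
  tal <- tallyStrandCounts(ct)
  expect_equal(sum(tal), 2L)                   # two families tallied
})
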