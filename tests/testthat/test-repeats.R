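test_that("hairpin enumeration tiles the strand set", {
  st <- seq(10, 160, by = 20)
  topo <- BetaTopology(IRanges::IRanges(st, st + 9))  # 8 strands
  s <- strrep("A", 200)
  disj <- enumerateHairpins(topo, s)
  expect_equal(nrow(disj), 4L)
  expect_equal(disj$strand1, c(1L, 3L, 5L, 7L))
  # disjoint units never share a strand
  expect_equal(anyDuplicated(c(disj$strand1, disj$strand2)), 0L)
  slid <- enumerateHairpins(topo, s, mode = "sliding")
  expect_equal(nrow(slid), 7L)
  # three strands, disjoint mode: one unit; below two strands: none
  topo3 <- BetaTopology(IRanges::IRanges(c(10, 30, 50), c(19, 39, 59)))
  expect_equal(nrow(enumerateHairpins(topo3, s)), 1L)
  topo1 <- BetaTopology(IRanges::IRanges(10, 19))
  expect_equal(nrow(enumerateHairpins(topo1, s)), 0L)
})

test_that("an exact tandem duplication is the top hit at minimal p", {
  set.seed(61)
  # one full hairpin (strand-turn-strand) duplicated in tandem, plus a
  # third unrelated hairpin downstream
  hp <- paste0(randomAA(12), randomAA(4), randomAA(12))   # 28 aa
  other <- paste0(randomAA(12), randomAA(4), randomAA(12))
  s <- paste0(randomAA(20), hp, randomAA(6), hp, randomAA(6), other,
              randomAA(20))
  st <- c(21, 37, 55, 71, 89, 105)
  topo <- BetaTopology(IRanges::IRanges(st, st + 11L))
  n <- 500L
  hits <- hairpinRepeatScan(s, topo, nShuffles = n, seed = 5)
  expect_equal(hits$unitA[1], 1L)
  expect_equal(hits$unitB[1], 2L)
  expect_equal(hits$empiricalP[1], 1 / (n + 1))
})

test_that("scan output is independent of unit enumeration order", {
  anc <- makeAncestor(barrelSpec(6L, amplifiedUnit = list(
    unit = 2L, nCopies = 3L, divergence = 0.2)), seed = 63)
  h1 <- hairpinRepeatScan(anc$seq, anc$topology, nShuffles = 200, seed = 7)
  # rebuild the topology from a reversed IRanges input; BetaTopology
  # sorts, so the scan must see identical units
  topo2 <- BetaTopology(rev(strandRanges(anc$topology)))
  h2 <- hairpinRepeatScan(anc$seq, topo2, nShuffles = 200, seed = 7)
  expect_equal(h1, h2)
})

test_that("sensitivity decreases with repeat divergence", {
  sep <- vapply(c(0.2, 0.4, 0.6), function(d) {
    vals <- vapply(1:4, function(s) {
      anc <- makeAncestor(barrelSpec(8L, amplifiedUnit = list(
        unit = 3L, nCopies = 4L, divergence = d)), seed = 640 + s)
      hits <- hairpinRepeatScan(anc$seq, anc$topology, nShuffles = 300,
                                seed = s)
      isAmp <- hits$unitA %in% 3:6 & hits$unitB %in% 3:6
      mean(hits$z[isAmp]) - mean(hits$z[!isAmp])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(sep) < 0))
})

test_that("barrels without amplification report no repeats", {
  # i.i.d. strands: no unit pair should look like a repeat
  fp <- vapply(1:5, function(s) {
    anc <- makeAncestor(barrelSpec(8L), seed = 650 + s)
    hits <- hairpinRepeatScan(anc$seq, anc$topology, nShuffles = 999,
                              seed = s)
    any(hits$empiricalP < 0.005)
  }, logical(1))
  expect_lte(sum(fp), 1L)
})
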