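test_that("generation is fully reproducible from the seed", {
  a1 <- makeAncestor(barrelSpec(8L), seed = 5)
  a2 <- makeAncestor(barrelSpec(8L), seed = 5)
  expect_identical(a1$seq, a2$seq)
  f1 <- evolveFamily(a1, familySpec(5L, targetIdentity = 0.5, seed = 9))
  f2 <- evolveFamily(a2, familySpec(5L, targetIdentity = 0.5, seed = 9))
  expect_identical(chr(f1), chr(f2))
  # byte-identical FASTA output
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeFastaSet(f1, p1); writeFastaSet(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted strand counts and lengths follow the spec", {
  anc <- makeAncestor(barrelSpec(nHairpins = 8L, strandLen = 10L),
                      seed = 2)
  expect_equal(nStrands(anc$topology), 16L)
  expect_true(all(IRanges::width(strandRanges(anc$topology)) == 10L))
  # protein sizes span the plausible barrel range across hairpin counts
  lens <- vapply(4:14, function(nh)
    nchar(makeAncestor(barrelSpec(nh), seed = nh)$seq), numeric(1))
  expect_true(all(lens > 150 & lens < 1400))
  expect_true(all(diff(lens) > 0) || cor(4:14, lens) > 0.9)
})

test_that("planted strands alternate in hydropathy", {
  anc <- makeAncestor(barrelSpec(8L), seed = 6)
  kd <- hydropathyScale()
  acs <- vapply(seq_len(nStrands(anc$topology)), function(k) {
    sp <- strandRanges(anc$topology)[k]
    h <- kd[strsplit(substr(anc$seq, IRanges::start(sp),
                            IRanges::end(sp)), "")[[1]]]
    cor(h[-length(h)], h[-1])   # lag-1 autocorrelation
  }, numeric(1))
  expect_lt(mean(acs), 0)
})

test_that("zero divergence reproduces the ancestor exactly", {
  anc <- makeAncestor(barrelSpec(6L), seed = 3)
  fam <- evolveFamily(anc, familySpec(4L, targetIdentity = 0.999,
                                      seed = 1))
  expect_true(all(chr(fam) == anc$seq))
})

test_that("the realized identity hits the target within tolerance", {
  anc <- makeAncestor(barrelSpec(9L), seed = 4)
  fam <- evolveFamily(anc, familySpec(6L, targetIdentity = 0.40,
                                      seed = 2))
  ids <- combn(6, 2)
  idy <- apply(ids[, sample(ncol(ids), 8)], 2, function(p)
    pairIdentity(chr(fam)[p[1]], chr(fam)[p[2]]))
  expect_gte(mean(idy), 0.33)
  expect_lte(mean(idy), 0.47)
})

test_that("indels stay in loops: planted strand residues survive intact", {
  anc <- makeAncestor(barrelSpec(7L), seed = 8)
  fam <- evolveFamily(anc, familySpec(4L, targetIdentity = 0.95,
                                      seed = 3))
  truth <- S4Vectors::metadata(fam)$strandRanges
  for (i in seq_along(fam)) {
    tp <- truth[[i]]
    expect_equal(length(tp), nStrands(anc$topology))
    expect_true(all(IRanges::width(tp) == 10L))
    expect_true(max(IRanges::end(tp)) <= nchar(chr(fam)[i]))
  }
  # lengths vary (loop indels) while strand count is untouched
  fam2 <- evolveFamily(anc, familySpec(6L, targetIdentity = 0.5,
                                       indelRate = 0.05, seed = 4))
  expect_gt(length(unique(nchar(chr(fam2)))), 1L)
})

test_that("amplified hairpins are mutually more similar than background", {
  anc <- makeAncestor(barrelSpec(8L, amplifiedUnit = list(
    unit = 3L, nCopies = 4L, divergence = 0.25)), seed = 12)
  expect_equal(anc$amplified, 3:6)
  hits <- hairpinRepeatScan(anc$seq, anc$topology, nShuffles = 300,
                            seed = 1)
  isAmp <- hits$unitA %in% 3:6 & hits$unitB %in% 3:6
  expect_gt(mean(hits$z[isAmp]), mean(hits$z[!isAmp]))
})

test_that("superfamily generation emits families, truth tree and labels", {
  sf <- makeSuperfamily(superfamilySpec("((A:0.2,B:0.2):0.1,C:0.4);",
                                        nMembers = 3L,
                                        targetIdentity = 0.6, seed = 7,
                                        barrel = barrelSpec(8L)))
  expect_setequal(names(sf$families), c("A", "B", "C"))
  expect_s3_class(sf$tree, "phylo")
  expect_equal(nrow(sf$membership), 9L)
  # near-zero divergence between two families makes them cross-detectable
  sf2 <- makeSuperfamily(superfamilySpec("(A:0.02,B:0.02);",
                                         nMembers = 2L,
                                         targetIdentity = 0.8, seed = 11,
                                         barrel = barrelSpec(8L)))
  r <- segmentShuffleZ(chr(sf2$families$A)[1], chr(sf2$families$B)[1],
                       nShuffles = 300, seed = 1)
  expect_gt(zSD(r$z), 12)
})

test_that("hairpin turnover changes strand counts by whole hairpins", {
  anc <- makeAncestor(barrelSpec(8L), seed = 13)
  fam <- evolveFamily(anc, familySpec(12L, targetIdentity = 0.9,
                                      hairpinTurnover = 1,
                                      seed = 6))
  counts <- vapply(S4Vectors::metadata(fam)$strandRanges, length,
                   integer(1))
  expect_true(all(counts %% 2L == 0L))          # whole hairpins only
  expect_true(all(abs(counts - 16L) == 2L))     # one event per member here
  expect_true(any(counts == 14L) && any(counts == 18L))
})
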