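test_that("family expansion finds two-hop neighbours only at the loose cutoff", {
  set.seed(41)
  # planted two-hop structure: seed ~ intermediate ~ target, with the
  # seed-target pair too diverged for a one-hop hit
  # I sits halfway along the path from the seed family S0 to the target
  # family T (S0-I and I-T at 0.45 substitutions/site, S0-T at 0.9)
  sfI <- makeSuperfamily(superfamilySpec(
    "(S0:0.001,(I:0.0001,T:0.45):0.45);",
    nMembers = 2L, targetIdentity = 0.95, seed = 9,
    barrel = barrelSpec(8L)))
  db <- makeSeqSet(c(chr(sfI$families$S0), chr(sfI$families$I),
                     chr(sfI$families$T),
                     chr(randomSeqSet(3, 300, "membrane", seed = 3,
                                      prefix = "decoy"))))
  seedId <- names(sfI$families$S0)[1]
  twoHop <- expandFamily(seedId, db, iterations = 2L,
                         cutoffs = c(1e-4, 1e-6))
  oneHopStrict <- expandFamily(seedId, db, iterations = 1L,
                               cutoffs = 1e-100)
  expect_true(any(names(sfI$families$I) %in% names(twoHop)))
  expect_true(any(names(sfI$families$T) %in% names(twoHop)))
  expect_false(any(grepl("^decoy", names(twoHop))))
  # at an extreme cutoff only the seed family itself survives
  expect_true(all(grepl("^S0", names(oneHopStrict))))
  # second pass never admits a sequence whose best E-value is above the
  # second cutoff: everything gathered is reachable at 1e-6 from a
  # first-pass member
  ka <- ompbarrel:::kaParams()
  for (id in setdiff(names(twoHop), seedId)) {
    ev <- vapply(setdiff(names(twoHop), id), function(q) {
      s <- alnScore(localAlign(chr(db)[q], chr(db)[id]))
      ompbarrel:::evalueOf(s, nchar(chr(db)[q]), sum(nchar(chr(db))), ka)
    }, numeric(1))
    expect_lte(min(ev), 1e-4)
  }
})

test_that("the candidate screen ranks pairs exactly as the score table", {
  set.seed(42)
  a <- randomSeqSet(5, 120, "membrane", seed = 1, prefix = "a")
  b <- randomSeqSet(5, 120, "membrane", seed = 2, prefix = "b")
  top <- screenPairs(a, b, topK = Inf)
  expect_equal(nrow(top), 25L)
  # exhaustive recomputation pair by pair
  for (k in seq_len(nrow(top)))
    expect_equal(top$score[k],
                 alnScore(localAlign(chr(a)[top$idA[k]],
                                     chr(b)[top$idB[k]])))
  expect_true(all(diff(top$score) <= 0))
  # the self-pair ranks first when the sets coincide
  selfTop <- screenPairs(a, a, topK = 1L)
  expect_identical(selfTop$idA, selfTop$idB)
})

test_that("chains accept trivially on identity and reject short proteins", {
  set.seed(43)
  s <- setNames(randomAA(100), "p1")
  ch <- verifyChain(s, s, s, s, nShuffles = 100, seed = 1)
  expect_true(isAccepted(ch))
  short <- setNames(randomAA(40), "tiny")
  ch2 <- verifyChain(short, s, s, s, nShuffles = 100, seed = 1)
  expect_false(isAccepted(ch2))
  expect_match(ch2@reason, "below 60")
})

test_that("superfamily components equal a DFS oracle on random graphs", {
  set.seed(44)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    fams <- paste0("F", seq_len(n))
    nE <- sample(0:(n + 2), 1)
    ea <- sample(fams, nE, replace = TRUE)
    eb <- sample(fams, nE, replace = TRUE)
    keep <- ea != eb
    ev <- data.frame(familyA = ea[keep], familyB = eb[keep])
    sfa <- buildSuperfamilies(ev, fams)
    oracle <- dfsComponents(fams, ev$familyA, ev$familyB)
    got <- superfamilyOf(sfa)
    # identical partitions (labels may differ)
    expect_equal(length(unique(got)), length(unique(oracle)))
    for (f1 in fams) for (f2 in fams)
      expect_identical(got[f1] == got[f2], oracle[f1] == oracle[f2],
                       info = paste(rep, f1, f2))
  }
})

test_that("assignment is order-independent and never asserts non-membership", {
  ev <- data.frame(familyA = c("A", "B", "X"), familyB = c("B", "C", "Y"))
  fams <- c("A", "B", "C", "X", "Y", "Z")
  s1 <- buildSuperfamilies(ev, fams)
  s2 <- buildSuperfamilies(ev[c(3, 1, 2), ], rev(fams))
  expect_identical(superfamilyOf(s1)[fams], superfamilyOf(s2)[fams])
  # the isolated family is "no evidence", not "not a member"
  expect_identical(unname(s1@status["Z"]), "no evidence")
  expect_identical(unname(s1@status["A"]), "assigned")
  # empty evidence: every family its own component
  s0 <- buildSuperfamilies(NULL, fams)
  expect_equal(length(unique(superfamilyOf(s0))), length(fams))
})

test_that("chain reports carry the four ids and three link scores", {
  set.seed(45)
  s <- setNames(randomAA(100), "p")
  ch <- verifyChain(s, s, s, s, nShuffles = 100, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeChainReport(list(ch), f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_named(tab, c("proteinA", "proteinB", "proteinC", "proteinD",
                      "z_AB", "z_BC", "z_CD", "z_AD", "accepted",
                      "method"))
})
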