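test_that("the bit-score matrix matches pair-by-pair recomputation", {
  set.seed(51)
  s <- randomSeqSet(4, 100, "membrane", seed = 1)
  sm <- allVsAllScores(s)
  raw <- attr(sm@bits, "raw")
  for (i in 1:4) for (j in 1:4)
    expect_equal(raw[i, j], alnScore(localAlign(chr(s)[i], chr(s)[j])))
  # local score bound: no pair outscores either self-comparison
  for (i in 1:4) for (j in 1:4)
    expect_lte(raw[i, j], min(raw[i, i], raw[j, j]))
  expect_error(allVsAllScores(s[1:2]), "at least 3")
})

test_that("distances are zero for identical, one for unrelated, monotone", {
  s <- randomSeqSet(3, 80, seed = 2)
  x <- makeSeqSet(c(a = chr(s)[[1]], b = chr(s)[[1]], c = chr(s)[[2]]))
  d <- as.matrix(scoresToDistances(allVsAllScores(x)))
  expect_equal(d["a", "b"], 0)
  # saturation for a non-positive raw score
  y <- makeSeqSet(c(p = strrep("P", 60), w = strrep("W", 60),
                    g = strrep("G", 60)))
  dy <- as.matrix(scoresToDistances(allVsAllScores(y)))
  expect_equal(dy["p", "w"], 1)
  # monotonicity: raising an off-diagonal score never raises its distance
  sm <- allVsAllScores(randomSeqSet(4, 90, seed = 3))
  d0 <- as.matrix(scoresToDistances(sm))
  sm2 <- sm
  sm2@bits[1, 2] <- sm2@bits[2, 1] <- sm2@bits[1, 2] + 5
  attr(sm2@bits, "raw")[1, 2] <- attr(sm2@bits, "raw")[2, 1] <-
    attr(sm2@bits, "raw")[1, 2] + 5
  d1 <- as.matrix(scoresToDistances(sm2))
  expect_lte(d1[1, 2], d0[1, 2])
})

test_that("neighbor joining recovers additive matrices exactly", {
  # 4-taxon additive matrix from tree ((a:2,b:3):1,(c:4,d:5))
  tr <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:5):1);")
  d <- cophenetic(tr)
  nj <- njTree(d)
  expect_equal(rfDistance(nj, tr), 0)
  expect_equal(sum(nj$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  # degenerate star input still yields a valid tree
  ds <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(ds) <- 0
  star <- njTree(ds)
  expect_s3_class(star, "phylo")
  expect_setequal(star$tip.label, letters[1:4])
  expect_error(njTree(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("NJ topology agrees with exhaustive least-squares search", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (rep in 1:5) {
    tr <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    tr <- ape::unroot(tr)
    d <- cophenetic(tr) + matrix(runif(25, 0, 0.02), 5)
    d <- (d + t(d)) / 2; diag(d) <- 0
    expect_equal(rfDistance(njTree(d), lsBestTopology(d)), 0)
  }
})

test_that("noise-free replicates reproduce the point tree at full support", {
  set.seed(54)
  sf <- makeSuperfamily(superfamilySpec("((A:0.15,B:0.15):0.1,C:0.4);",
                                        nMembers = 2L,
                                        targetIdentity = 0.7, seed = 3,
                                        barrel = barrelSpec(8L)))
  pool <- makeSeqSet(unlist(unname(lapply(sf$families, chr))))
  cons <- consensusTree(pool, nReplicates = 10, seed = 1,
                        strategy = "none")
  expect_equal(rfDistance(cons, attr(cons, "pointTree")), 0)
  sup <- as.numeric(cons$node.label)
  expect_true(all(sup[is.finite(sup)] == 100))
  # leaf input order does not change the consensus topology
  cons2 <- consensusTree(pool[rev(seq_along(pool))], nReplicates = 10,
                         seed = 1, strategy = "none")
  expect_equal(rfDistance(cons, cons2), 0)
})

test_that("families stay monophyletic with high support on synthetic data", {
  sf <- makeSuperfamily(superfamilySpec("((A:0.2,B:0.2):0.12,C:0.45);",
                                        nMembers = 4L,
                                        targetIdentity = 0.55, seed = 8,
                                        barrel = barrelSpec(9L)))
  pool <- makeSeqSet(unlist(unname(lapply(sf$families, chr))))
  groups <- split(sf$membership$id, sf$membership$family)
  cons <- consensusTree(pool, nReplicates = 50, seed = 2)
  expect_true(all(isMonophyletic(cons, groups)))
})

test_that("a family duplicated under two names pairs with itself", {
  sf <- makeSuperfamily(superfamilySpec("((A:0.15,B:0.15):0.1,C:0.4);",
                                        nMembers = 5L,
                                        targetIdentity = 0.6, seed = 4,
                                        barrel = barrelSpec(8L)))
  fams <- sf$families
  fams$Bcopy <- makeSeqSet(setNames(chr(fams$B),
                                    paste0("copy_", names(fams$B))))
  ft <- suppressWarnings(familyTree(fams, nReplicates = 20, seed = 1))
  pt <- attr(ft, "pointTree")
  # the duplicate is its original's closest relative and its sister tip
  cp <- cophenetic(pt)
  expect_equal(names(which.min(cp["Bcopy", setdiff(colnames(cp),
                                                   "Bcopy")])), "B")
  expect_true(isMonophyletic(pt, list(bb = c("B", "Bcopy")))[["bb"]])
  expect_error(familyTree(fams[1:2]), "at least 3")
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  sf <- makeSuperfamily(superfamilySpec("((A:0.15,B:0.15):0.1,C:0.4);",
                                        nMembers = 5L,
                                        targetIdentity = 0.6, seed = 6,
                                        barrel = barrelSpec(8L)))
  ft <- suppressWarnings(familyTree(sf$families, nReplicates = 20,
                                    seed = 1))
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(ft, f)
  back <- ape::read.tree(f)
  expect_equal(rfDistance(ft, back), 0)
  expect_equal(sort(back$edge.length), sort(ft$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, ft$node.label)
})

test_that("consensus trees are stable across seeds", {
  sf <- makeSuperfamily(superfamilySpec(
    "((A:0.12,B:0.12):0.08,(C:0.12,D:0.12):0.08,E:0.3);",
    nMembers = 5L, targetIdentity = 0.55, seed = 10,
    barrel = barrelSpec(9L)))
  t1 <- suppressWarnings(familyTree(sf$families, nReplicates = 50,
                                    seed = 1))
  t2 <- suppressWarnings(familyTree(sf$families, nReplicates = 50,
                                    seed = 999))
  expect_lte(rfDistance(t1, t2), 2)
})
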