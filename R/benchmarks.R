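# Standard validation benchmarks.
#
# These functions freeze the study conditions under which the pipeline is
# validated: null calibration on composition-biased non-homologues,
# transitive-chain recovery on a calibrated 3-family path, superfamily
# partition recovery on a planted 2-superfamily / 6-family world, family
# tree recovery on a 5-family guide tree, strand-caller accuracy on
# barrels spanning the 8-28-strand range, and hairpin-repeat detection
# with its i.i.d. null. The same runners back the unit tests and the
# acceptance script, so every reported number is recomputed from scratch.

#' Null calibration of the comparison score
#'
#' Generates pairs of unrelated, composition-biased 200-mers (70\% of
#' residues from I/L/V/F) and computes the full-sequence comparison score
#' for each pair. For a calibrated statistic the scores are centred on
#' zero regardless of the shared biased composition, and no unrelated
#' pair reaches the 12 SD evidence threshold.
#'
#' @param nPairs number of sequence pairs (default 1000).
#' @param length sequence length (200, comfortably above the 60-residue
#'   evidence rule).
#' @param nShuffles shuffles per pair (200: the score is stable to well
#'   under 0.1 SD at this depth, and a thousand pairs stay cheap).
#' @param seed integer seed.
#' @return data.frame with one row per pair: \code{z}.
#' @export
benchNullCalibration <- function(nPairs = 1000L, length = 200L,
                                 nShuffles = 200L, seed = 1L) {
  seqs <- randomSeqSet(2L * nPairs, length, composition = "biased",
                       seed = deriveSeed(seed, 1L))
  sq <- asNamedChar(seqs)
  z <- vapply(seq_len(nPairs), function(i) {
    r <- shuffleZ(sq[2L * i - 1L], sq[2L * i], nShuffles = nShuffles,
                  seed = deriveSeed(seed, 10L + i))
    if (r@degenerate) NA_real_ else zSD(r)
  }, numeric(1))
  data.frame(pair = seq_len(nPairs), z = z)
}

#' Transitive-chain benchmark
#'
#' Three families on a path guide tree (per-site substitution 0.8 on
#' each terminal edge, so adjacent families sit near 30\% identity and
#' the two end families near 20\%): links are calibrated to comparison
#' scores around 20 SD while the direct end-to-end comparison falls below
#' the 12 SD threshold. Bridge and end members are chosen as the
#' top-ranked cross-family local-score pairs, mirroring the protocol of
#' confirming the top rapid-search scores.
#'
#' @param nSeeds number of independent replicates.
#' @param nShuffles shuffles per comparison.
#' @param seed master seed.
#' @return data.frame per seed: \code{chainAccepted} (all three links
#'   exceed 12 SD), \code{directZ}, \code{directRejected}, link scores.
#' @export
benchChain <- function(nSeeds = 20L, nShuffles = 1000L, seed = 1L) {
  out <- lapply(seq_len(nSeeds), function(s) {
    sf <- makeSuperfamily(superfamilySpec(
      "(A:0.8,B:0.001,C:0.8);", nMembers = 4L, targetIdentity = 0.55,
      seed = deriveSeed(seed, 600L + s), barrel = barrelSpec(9L)))
    A <- sf$families$A; B <- sf$families$B; C <- sf$families$C
    tAB <- screenPairs(A, B, topK = 1L)
    tBC <- screenPairs(B, C, topK = 1L)
    a <- setNames(as.character(A[tAB$idA]), tAB$idA)
    b <- setNames(as.character(B[tAB$idB]), tAB$idB)
    b2 <- setNames(as.character(B[tBC$idA]), tBC$idA)
    cc <- setNames(as.character(C[tBC$idB]), tBC$idB)
    ch <- verifyChain(a, b, b2, cc, nShuffles = nShuffles,
                      seed = deriveSeed(seed, 700L + s))
    lz <- zSD(ch)
    data.frame(seed = s,
               chainAccepted = isAccepted(ch) && ch@method == "chained",
               directZ = ch@directZ,
               directRejected = is.na(ch@directZ) || ch@directZ < 12,
               zAB = if (length(lz)) lz[1] else NA_real_,
               zBC = if (length(lz) > 1) lz[2] else NA_real_,
               zCD = if (length(lz) > 2) lz[3] else NA_real_)
  })
  do.call(rbind, out)
}

# The planted two-superfamily world: two independent root ancestors (9-
# and 10-hairpin barrels), three families each on a
# ((X:0.2, Y:0.2):0.1, Z:0.35) guide tree, 4 members per family at 55%
# within-family identity.
benchPartitionFamilies <- function(seed) {
  s1 <- makeSuperfamily(superfamilySpec(
    "((A:0.2,B:0.2):0.1,C:0.35);", nMembers = 4L, targetIdentity = 0.55,
    seed = deriveSeed(seed, 1L), barrel = barrelSpec(9L)))
  s2 <- makeSuperfamily(superfamilySpec(
    "((D:0.2,E:0.2):0.1,F:0.35);", nMembers = 4L, targetIdentity = 0.55,
    seed = deriveSeed(seed, 2L), barrel = barrelSpec(10L)))
  c(s1$families, s2$families)
}

#' Superfamily partition benchmark
#'
#' Runs the full cross-family screen on the planted 2-superfamily /
#' 6-family world and scores exact partition recovery and false merges
#' (any accepted evidence joining the two independent superfamilies).
#'
#' @param nSeeds number of replicates.
#' @param nShuffles shuffles per confirmed comparison.
#' @param seed master seed.
#' @return data.frame per seed: \code{exact}, \code{falseMerge}.
#' @export
benchPartition <- function(nSeeds = 20L, nShuffles = 500L, seed = 1L) {
  truth1 <- c("A", "B", "C"); truth2 <- c("D", "E", "F")
  out <- lapply(seq_len(nSeeds), function(s) {
    fams <- benchPartitionFamilies(deriveSeed(seed, 300L + s))
    sc <- screenFamilies(fams, nShuffles = nShuffles,
                         seed = deriveSeed(seed, 400L + s))
    comp <- superfamilyOf(buildSuperfamilies(sc$edges, names(fams)))
    exact <- length(unique(comp[truth1])) == 1L &&
      length(unique(comp[truth2])) == 1L && comp["A"] != comp["D"]
    fm <- nrow(sc$edges) > 0L &&
      any((sc$edges$familyA %in% truth1) != (sc$edges$familyB %in% truth1))
    data.frame(seed = s, exact = exact, falseMerge = fm)
  })
  do.call(rbind, out)
}

.TREE_BENCH_GUIDE <- "((A:0.12,B:0.12):0.08,(C:0.12,D:0.12):0.08,E:0.3);"
.TREE_BENCH_GUIDE_HI <- "((A:0.7,B:0.7):0.4,(C:0.7,D:0.7):0.4,E:1.4);"

#' Family-tree benchmark
#'
#' Moderate-divergence regime: five families (5 members each) on a known
#' guide tree; the score-based family tree should recover the guide
#' topology exactly with high consensus support. High-divergence regime:
#' the same shape at roughly triple the divergence, where the
#' conventional progressive-MSA tree starts scattering families while the
#' score-based protein tree keeps them monophyletic.
#'
#' @param nSeeds replicates.
#' @param nReplicates consensus replicates per tree.
#' @param seed master seed.
#' @param high run the high-divergence MSA-contrast regime too.
#' @return data.frame per seed: \code{rf} (Robinson-Foulds distance of
#'   the family tree to the guide tree), \code{minSupport} (lowest
#'   consensus support over internal edges), and, when \code{high},
#'   \code{scoreMono} / \code{msaMono} (numbers of monophyletic families
#'   out of 5 in the high-divergence regime).
#' @export
benchFamilyTree <- function(nSeeds = 10L, nReplicates = 100L, seed = 1L,
                            high = TRUE) {
  out <- lapply(seq_len(nSeeds), function(s) {
    sf <- makeSuperfamily(superfamilySpec(
      .TREE_BENCH_GUIDE, nMembers = 5L, targetIdentity = 0.55,
      seed = deriveSeed(seed, 500L + s), barrel = barrelSpec(9L)))
    ft <- suppressWarnings(familyTree(sf$families,
                                      nReplicates = nReplicates,
                                      seed = deriveSeed(seed, 550L + s)))
    sup <- suppressWarnings(as.numeric(ft$node.label))
    sup <- sup[is.finite(sup)][-1]   # drop the root pseudo-node
    row <- data.frame(seed = s, rf = rfDistance(ft, sf$tree),
                      minSupport = if (length(sup)) min(sup) else NA_real_)
    if (high) {
      sfh <- makeSuperfamily(superfamilySpec(
        .TREE_BENCH_GUIDE_HI, nMembers = 5L, targetIdentity = 0.22,
        seed = deriveSeed(seed, 560L + s), barrel = barrelSpec(9L)))
      pool <- makeSeqSet(unlist(unname(lapply(sfh$families, asNamedChar))))
      groups <- split(sfh$membership$id, sfh$membership$family)
      st <- consensusTree(pool, nReplicates = 30L,
                          seed = deriveSeed(seed, 570L + s))
      row$scoreMono <- sum(isMonophyletic(attr(st, "pointTree"), groups))
      row$msaMono <- sum(isMonophyletic(msaTree(pool), groups))
    }
    row
  })
  do.call(rbind, out)
}

#' Strand-caller benchmark
#'
#' Fifty synthetic barrels spanning 4-14 hairpins (8-28 strands).
#' Residue-level recall of the planted strands is measured on each
#' ancestor; the reported strand count per barrel is the family-consensus
#' (modal) call over a small evolved family, the intended use of the
#' caller.
#'
#' @param nBarrels number of barrels.
#' @param nMembers members per family for the modal count.
#' @param seed master seed.
#' @return data.frame per barrel: \code{nHairpins}, \code{planted} (2 x
#'   hairpins), \code{recall}, \code{modal} (family-modal called count).
#' @export
benchTopology <- function(nBarrels = 50L, nMembers = 5L, seed = 1L) {
  out <- lapply(seq_len(nBarrels), function(i) {
    nh <- withSeed(deriveSeed(seed, 80L + i), sample(4:14, 1L))
    anc <- makeAncestor(barrelSpec(nHairpins = nh),
                        seed = deriveSeed(seed, 800L + i),
                        id = sprintf("bar%02d", i))
    truth <- strandRanges(anc$topology)
    called <- strandRanges(predictBetaTms(anc$seq))
    tv <- cv <- rep(FALSE, nchar(anc$seq))
    tv[unlist(Map(seq.int, IRanges::start(truth),
                  IRanges::end(truth)))] <- TRUE
    if (length(called))
      cv[unlist(Map(seq.int, IRanges::start(called),
                    IRanges::end(called)))] <- TRUE
    fam <- evolveFamily(anc, familySpec(nMembers, targetIdentity = 0.6,
                                        seed = deriveSeed(seed, 900L + i)))
    modal <- countTmsByFamily(list(f = fam))$summary$modal_strands
    data.frame(barrel = i, nHairpins = nh, planted = 2L * nh,
               nResiduesTrue = sum(tv), nResiduesHit = sum(tv & cv),
               recall = sum(tv & cv) / sum(tv), modal = modal)
  })
  do.call(rbind, out)
}

#' Hairpin-repeat benchmark
#'
#' Amplified regime: 8-hairpin barrels whose hairpins 3-6 are copies of
#' one ancestral unit at 30\% pairwise divergence; the scan should rank
#' every amplified unit pair above every background pair. Null regime:
#' i.i.d. membrane-composition sequences with an arbitrary tiling of
#' pseudo-hairpin windows; no pair should reach an empirical P below
#' 0.001.
#'
#' @param nSeeds replicates per regime.
#' @param nShuffles shuffles per unit pair (2000 in the null regime so
#'   that P = 0.001 is resolvable).
#' @param seed master seed.
#' @return list of two data.frames, \code{amplified} (per seed:
#'   \code{nAboveBackground} of 6) and \code{null} (per seed:
#'   \code{minP}, \code{anyBelow.001}).
#' @export
benchRepeat <- function(nSeeds = 20L, nShuffles = 2000L, seed = 1L) {
  amp <- lapply(seq_len(nSeeds), function(s) {
    anc <- makeAncestor(barrelSpec(8L, amplifiedUnit = list(
      unit = 3L, nCopies = 4L, divergence = 0.3)),
      seed = deriveSeed(seed, 30L + s))
    hits <- hairpinRepeatScan(anc$seq, anc$topology,
                              nShuffles = nShuffles,
                              seed = deriveSeed(seed, 60L + s))
    isAmp <- hits$unitA %in% 3:6 & hits$unitB %in% 3:6
    data.frame(seed = s,
               nAboveBackground = sum(hits$z[isAmp] >
                                        max(hits$z[!isAmp])))
  })
  null <- lapply(seq_len(nSeeds), function(s) {
    rs <- randomSeqSet(1L, 330L, composition = "membrane",
                       seed = deriveSeed(seed, 130L + s))
    st <- seq(20L, 300L, by = 20L)
    topo <- BetaTopology(IRanges::IRanges(start = st, end = st + 9L),
                         caller = "tiling")
    hits <- hairpinRepeatScan(as.character(rs[[1L]]), topo,
                              nShuffles = nShuffles,
                              seed = deriveSeed(seed, 160L + s))
    data.frame(seed = s, minP = min(hits$empiricalP),
               anyBelow.001 = any(hits$empiricalP < 0.001))
  })
  list(amplified = do.call(rbind, amp), null = do.call(rbind, null))
}
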