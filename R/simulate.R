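# Synthetic beta-barrel family generator.
#
# The generative model mirrors the amplification hypothesis for barrel
# evolution: a protein is a chain of beta-hairpin modules (strand - turn -
# strand - loop) flanked by terminal tails. Membrane-facing strand
# positions alternate hydrophobic / polar with period 2; loops are polar.
# Families are produced by evolving members independently from a common
# ancestor under a substitution process with loop-confined indels, with
# the per-site substitution rate calibrated by bisection so that the
# realized mean within-family identity matches a user-facing target.

.HYDRO_POOL <- c(I = 0.17, L = 0.19, V = 0.16, F = 0.12, A = 0.12,
                 W = 0.05, Y = 0.10, M = 0.09)
.POLAR_POOL <- c(G = 0.14, S = 0.16, T = 0.13, N = 0.10, Q = 0.08,
                 D = 0.09, E = 0.09, K = 0.09, R = 0.07, H = 0.05)
.LOOP_POOL  <- c(G = 0.13, S = 0.12, T = 0.09, N = 0.08, Q = 0.06,
                 D = 0.08, E = 0.07, K = 0.07, R = 0.06, H = 0.03,
                 P = 0.07, A = 0.06, Y = 0.03, F = 0.02, L = 0.03,
                 I = 0.02, V = 0.03, W = 0.01, M = 0.02, C = 0.02)

# Substitution proposal distribution derived from BLOSUM62: when a site
# mutates, the replacement b != a is drawn with probability proportional
# to 2^(s(a,b)/2).
.subProposal <- function() {
  if (!is.null(.pkg_env$subprop)) return(.pkg_env$subprop)
  m <- getSubMatrix("BLOSUM62")[1:20, 1:20]
  P <- 2^(m / 2)
  diag(P) <- 0
  P <- P / rowSums(P)
  .pkg_env$subprop <- P
  P
}

.sampleFromPool <- function(n, pool) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

#' Specification of a synthetic beta-barrel protein
#'
#' @param nHairpins number of beta-hairpins (4-14 gives the 8-28 strand
#'   range observed across OMPP families).
#' @param strandLen strand length in residues (default 10).
#' @param turnLenRange range of periplasmic turn lengths.
#' @param loopLenRange range of extracellular loop lengths.
#' @param tailLenRange range of N-/C-terminal tail lengths.
#' @param amplifiedUnit optional list \code{list(unit =, nCopies =,
#'   divergence =)}: hairpin \code{unit} and the following
#'   \code{nCopies - 1} hairpins are divergent copies of one ancestral
#'   hairpin; \code{divergence} is the expected pairwise divergence
#'   between copies (default 0.25).
#' @return a \code{BarrelSpec} list.
#' @export
barrelSpec <- function(nHairpins = 8L, strandLen = 10L,
                       turnLenRange = c(2L, 5L), loopLenRange = c(4L, 12L),
                       tailLenRange = c(5L, 25L), amplifiedUnit = NULL) {
  stopifnot(nHairpins >= 1L, strandLen >= 6L)
  if (!is.null(amplifiedUnit)) {
    amplifiedUnit$divergence <- amplifiedUnit$divergence %||% 0.25
    stopifnot(amplifiedUnit$unit >= 1L,
              amplifiedUnit$unit + amplifiedUnit$nCopies - 1L <= nHairpins)
  }
  structure(list(nHairpins = as.integer(nHairpins),
                 strandLen = as.integer(strandLen),
                 turnLenRange = as.integer(turnLenRange),
                 loopLenRange = as.integer(loopLenRange),
                 tailLenRange = as.integer(tailLenRange),
                 amplifiedUnit = amplifiedUnit),
            class = "BarrelSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strand residues alternate membrane-facing / lumen-facing. Real strands
# are imperfectly amphipathic: membrane-facing positions are hydrophobic
# with high (not certain) probability and lumen-facing positions are only
# weakly constrained, so the alternation carries noise by design.
.STRAND_FACE_P <- c(membrane = 0.85, lumen = 0.70)

.newStrand <- function(len) {
  res <- character(len)
  for (i in seq_len(len)) {
    if (i %% 2L == 1L) {
      pool <- if (runif(1) < .STRAND_FACE_P["membrane"]) .HYDRO_POOL
              else .POLAR_POOL
    } else {
      pool <- if (runif(1) < .STRAND_FACE_P["lumen"]) .POLAR_POOL
              else .HYDRO_POOL
    }
    res[i] <- sample(names(pool), 1L, prob = pool)
  }
  res
}

.strandClassPool <- function(pos) {
  if (pos %% 2L == 1L) .HYDRO_POOL else .POLAR_POOL
}

# Mutate a segment character vector at per-site probability p.
# Strand sites keep their hydropathy class with probability classKeep so
# the amphipathic alternation survives divergence (membrane constraint).
.mutateChars <- function(chars, p, type, classKeep = 0.85) {
  if (length(chars) == 0L || p <= 0) return(chars)
  hit <- which(runif(length(chars)) < p)
  if (!length(hit)) return(chars)
  P <- .subProposal()
  for (i in hit) {
    cur <- chars[i]
    pr <- P[cur, ]
    if (type == "strand" && runif(1) < classKeep) {
      # membrane constraint: restrict the BLOSUM-conditional proposal to
      # the residue class this strand position faces
      pool <- .strandClassPool(i)
      pr[!(colnames(P) %in% names(pool))] <- 0
      if (sum(pr) == 0) pr <- setNames(pool[names(pool) != cur],
                                       names(pool)[names(pool) != cur])
    }
    chars[i] <- sample(names(pr), 1L, prob = pr)
  }
  chars
}

# Apply loop-confined indels: per-site indel probability `rate`, geometric
# lengths (mean ~2.5), insertions drawn from the loop composition.
.indelLoop <- function(chars, rate, geomP = 0.4) {
  if (length(chars) == 0L || rate <= 0) return(chars)
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (runif(1) < rate) {
      len <- rgeom(1, geomP) + 1L
      if (runif(1) < 0.5) {            # deletion
        i <- i + len
        next
      } else {                         # insertion
        out <- c(out, .sampleFromPool(len, .LOOP_POOL), chars[i])
      }
    } else {
      out <- c(out, chars[i])
    }
    i <- i + 1L
  }
  if (length(out) == 0L) out <- .sampleFromPool(1L, .LOOP_POOL)
  out
}

.segmentsToSeq <- function(segments) {
  paste(vapply(segments, function(s) paste(s$chars, collapse = ""),
               character(1)), collapse = "")
}

.segmentsTopology <- function(segments, caller = "ground-truth") {
  lens <- vapply(segments, function(s) length(s$chars), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  keep <- vapply(segments, function(s) s$type == "strand", logical(1))
  BetaTopology(IRanges::IRanges(start = starts[keep], end = ends[keep]),
               caller = caller)
}

#' Generate a synthetic barrel ancestor with known topology
#'
#' Draws one beta-barrel-like protein from a \code{\link{barrelSpec}}:
#' alternating hydrophobic/polar strands, polar turns and loops, optional
#' amplified hairpin copies. The planted strand coordinates are returned
#' as ground truth.
#'
#' @param spec a \code{\link{barrelSpec}}.
#' @param seed integer seed.
#' @param id identifier for the ancestor.
#' @return a list of class \code{BarrelAncestor}: \code{seq} (character),
#'   \code{topology} (\code{\link{BetaTopology-class}} ground truth),
#'   \code{segments} (internal segment list), \code{amplified} (indices of
#'   hairpins that are copies of one unit, or integer(0)), \code{spec},
#'   \code{seed}.
#' @export
makeAncestor <- function(spec, seed = 1L, id = "anc") {
  stopifnot(inherits(spec, "BarrelSpec"))
  withSeed(as.integer(seed), {
    riN <- sample(spec$tailLenRange[1]:spec$tailLenRange[2], 1L)
    riC <- sample(spec$tailLenRange[1]:spec$tailLenRange[2], 1L)
    mkTurn <- function() list(type = "turn", chars = .sampleFromPool(
      sample(spec$turnLenRange[1]:spec$turnLenRange[2], 1L), .POLAR_POOL))
    mkLoop <- function() list(type = "loop", chars = .sampleFromPool(
      sample(spec$loopLenRange[1]:spec$loopLenRange[2], 1L), .LOOP_POOL))
    mkHairpin <- function() list(
      list(type = "strand", chars = .newStrand(spec$strandLen)),
      mkTurn(),
      list(type = "strand", chars = .newStrand(spec$strandLen)),
      mkLoop())
    hairpins <- replicate(spec$nHairpins, mkHairpin(), simplify = FALSE)
    amplified <- integer(0)
    au <- spec$amplifiedUnit
    if (!is.null(au)) {
      proto <- hairpins[[au$unit]]
      idx <- au$unit:(au$unit + au$nCopies - 1L)
      # `divergence` is the expected pairwise divergence BETWEEN copies
      # (the convention repeat-detection tools report); each copy mutates
      # from the prototype at the per-lineage rate that realizes it
      qCopy <- 1 - sqrt(1 - au$divergence)
      for (k in idx) {
        cp <- proto
        for (s in seq_along(cp))
          cp[[s]]$chars <- .mutateChars(cp[[s]]$chars, qCopy,
                                        cp[[s]]$type)
        hairpins[[k]] <- cp
      }
      amplified <- idx
    }
    segments <- c(list(list(type = "tail",
                            chars = .sampleFromPool(riN, .LOOP_POOL))),
                  do.call(c, hairpins),
                  list(list(type = "tail",
                            chars = .sampleFromPool(riC, .LOOP_POOL))))
    structure(list(seq = .segmentsToSeq(segments),
                   topology = .segmentsTopology(segments),
                   segments = segments, amplified = amplified,
                   spec = spec, seed = as.integer(seed), id = id),
              class = "BarrelAncestor")
  })
}

#' @export
print.BarrelAncestor <- function(x, ...) {
  cat("BarrelAncestor", x$id, ":", nchar(x$seq), "aa,",
      nStrands(x$topology), "planted strands",
      if (length(x$amplified))
        paste0("(hairpins ", paste(x$amplified, collapse = ","),
               " amplified)") else "", "\n")
  invisible(x)
}

#' Specification of a synthetic family
#'
#' @param nMembers number of members to evolve.
#' @param targetIdentity target mean pairwise identity among members
#'   (fraction in (0,1); identities over the shorter sequence).
#' @param indelRate per-site indel probability in loops/tails.
#' @param hairpinTurnover per-member probability of a whole-hairpin gain
#'   or loss event (strand-gain/loss mode: barrels are thought to grow
#'   and shrink by whole beta-hairpin units; default 0).
#' @param seed integer seed.
#' @return a \code{FamilySpec} list.
#' @export
familySpec <- function(nMembers = 10L, targetIdentity = 0.4,
                       indelRate = 0.01, hairpinTurnover = 0,
                       seed = 1L) {
  stopifnot(targetIdentity > 0, targetIdentity < 1, nMembers >= 2L,
            hairpinTurnover >= 0, hairpinTurnover <= 1)
  structure(list(nMembers = as.integer(nMembers),
                 targetIdentity = targetIdentity,
                 indelRate = indelRate,
                 hairpinTurnover = hairpinTurnover,
                 seed = as.integer(seed)),
            class = "FamilySpec")
}

# Whole-hairpin gain/loss: delete one hairpin module, or duplicate one in
# place. Segments are [tail, (strand,turn,strand,loop) x H, tail].
.hairpinGainLoss <- function(segments) {
  H <- (length(segments) - 2L) %/% 4L
  if (H < 2L) return(segments)
  k <- sample.int(H, 1L)
  idx <- (2L + 4L * (k - 1L)):(1L + 4L * k)
  if (runif(1) < 0.5) {
    segments[-idx]
  } else {
    append(segments, segments[idx], after = idx[length(idx)])
  }
}

# Membrane-spanning strands are under purifying selection and accept
# substitutions at a reduced relative rate compared to loops/turns.
.STRAND_RATE <- 0.6

# One evolved member: substitutions everywhere (strands at the reduced
# rate), indels only in loops and tails, so planted strand residues are
# preserved (coordinate-mapped).
.evolveMember <- function(segments, q, indelRate) {
  lapply(segments, function(s) {
    rate <- if (s$type == "strand") q * .STRAND_RATE else q
    ch <- .mutateChars(s$chars, rate, s$type)
    if (s$type %in% c("loop", "tail"))
      ch <- .indelLoop(ch, indelRate)
    list(type = s$type, chars = ch)
  })
}

.measuredIdentity <- function(segments, q, indelRate, nPairs = 2L,
                              params = alnParams()) {
  mean(vapply(seq_len(nPairs), function(i) {
    a <- .segmentsToSeq(.evolveMember(segments, q, indelRate))
    b <- .segmentsToSeq(.evolveMember(segments, q, indelRate))
    pairIdentity(a, b, params)
  }, numeric(1)))
}

#' Evolve a synthetic family from a barrel ancestor
#'
#' Members evolve independently from the ancestor (a star phylogeny):
#' substitutions are drawn from a BLOSUM62-derived proposal distribution
#' (class-conservative within planted strands), indels are geometric and
#' confined to loops and tails. The per-lineage substitution probability
#' is calibrated by bisection so that the realized mean pairwise identity
#' is within 5 points of \code{spec$targetIdentity}.
#'
#' @param ancestor a \code{BarrelAncestor} from \code{\link{makeAncestor}}.
#' @param spec a \code{\link{familySpec}}.
#' @param prefix member id prefix (default the ancestor id).
#' @return an \code{AAStringSet}; \code{mcols(.)$family} is the prefix and
#'   \code{metadata(.)} holds \code{strandRanges} (an
#'   \code{IRangesList} of ground-truth strand coordinates per member),
#'   \code{realizedIdentity} and the calibrated rate \code{q}.
#' @export
evolveFamily <- function(ancestor, spec, prefix = ancestor$id) {
  stopifnot(inherits(ancestor, "BarrelAncestor"), inherits(spec, "FamilySpec"))
  withSeed(spec$seed, {
    t <- spec$targetIdentity
    if (t >= 0.999) {
      q <- 0
    } else {
      lo <- 0; hi <- 0.95
      for (it in 1:9) {
        mid <- (lo + hi) / 2
        r <- .measuredIdentity(ancestor$segments, mid, spec$indelRate)
        if (r > t) lo <- mid else hi <- mid
      }
      q <- (lo + hi) / 2
      realized <- .measuredIdentity(ancestor$segments, q, spec$indelRate,
                                    nPairs = 3L)
      if (abs(realized - t) > 0.08)
        stop(sprintf(
          "identity target %.2f unattainable (calibrated to %.2f)",
          t, realized), call. = FALSE)
    }
    members <- lapply(seq_len(spec$nMembers), function(i) {
      segs <- ancestor$segments
      if (spec$hairpinTurnover > 0 && runif(1) < spec$hairpinTurnover)
        segs <- .hairpinGainLoss(segs)
      if (q == 0) segs else .evolveMember(segs, q, spec$indelRate)
    })
    ids <- sprintf("%s_m%02d", prefix, seq_len(spec$nMembers))
    seqs <- vapply(members, .segmentsToSeq, character(1))
    x <- makeSeqSet(setNames(seqs, ids),
                    sourceTag = sprintf("evolveFamily(%s)", prefix))
    S4Vectors::mcols(x)$family <- prefix
    truth <- IRanges::IRangesList(lapply(members, function(m)
      strandRanges(.segmentsTopology(m))))
    names(truth) <- ids
    S4Vectors::metadata(x)$strandRanges <- truth
    S4Vectors::metadata(x)$q <- q
    S4Vectors::metadata(x)$realizedIdentity <- if (q == 0) 1 else
      mean(vapply(utils::combn(min(4L, length(seqs)), 2L, simplify = FALSE),
                  function(pr) pairIdentity(seqs[pr[1]], seqs[pr[2]]),
                  numeric(1)))
    x
  })
}

#' Specification of a synthetic superfamily
#'
#' Families evolve along a binary guide tree whose edge lengths are
#' per-site substitution probabilities; each tip then expands into a
#' family via \code{\link{evolveFamily}}.
#'
#' @param guideTree a Newick string or \code{ape} \code{phylo} object with
#'   tip labels (family names) and edge lengths (per-site substitution
#'   probability along the edge).
#' @param barrel a \code{\link{barrelSpec}} for the root ancestor.
#' @param nMembers,targetIdentity,indelRate family-level settings applied
#'   at every tip.
#' @param seed master seed.
#' @return a \code{SuperfamilySpec} list.
#' @export
superfamilySpec <- function(guideTree, barrel = barrelSpec(),
                            nMembers = 8L, targetIdentity = 0.45,
                            indelRate = 0.01, seed = 1L) {
  tree <- if (inherits(guideTree, "phylo")) guideTree
          else ape::read.tree(text = guideTree)
  if (is.null(tree$edge.length))
    stop("guide tree must have edge lengths", call. = FALSE)
  structure(list(tree = tree, barrel = barrel,
                 nMembers = as.integer(nMembers),
                 targetIdentity = targetIdentity, indelRate = indelRate,
                 seed = as.integer(seed)),
            class = "SuperfamilySpec")
}

# Mutate a whole ancestor along one guide-tree edge (substitutions at
# per-site probability d; mild loop indels scale with d).
.mutateLineage <- function(segments, d, indelScale = 0.15) {
  lapply(segments, function(s) {
    rate <- if (s$type == "strand") d * .STRAND_RATE else d
    ch <- .mutateChars(s$chars, rate, s$type)
    if (s$type %in% c("loop", "tail"))
      ch <- .indelLoop(ch, d * indelScale)
    list(type = s$type, chars = ch)
  })
}

#' Generate a synthetic superfamily with known ground truth
#'
#' @param spec a \code{\link{superfamilySpec}}.
#' @return list with \code{families} (named list of \code{AAStringSet}),
#'   \code{tree} (the guide \code{phylo}, the true family tree),
#'   \code{membership} (data.frame id/family), and \code{ancestors}
#'   (per-family \code{BarrelAncestor}-like segment lists).
#' @export
makeSuperfamily <- function(spec) {
  stopifnot(inherits(spec, "SuperfamilySpec"))
  tree <- spec$tree
  root <- makeAncestor(spec$barrel, seed = deriveSeed(spec$seed, 0L),
                       id = "root")
  nTip <- length(tree$tip.label)
  rootNode <- nTip + 1L
  segAt <- vector("list", max(tree$edge))
  segAt[[rootNode]] <- root$segments
  ord <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # preorder: parents before children
  preord <- ape::reorder.phylo(tree, "cladewise")$edge
  withSeed(deriveSeed(spec$seed, 1L), {
    for (k in seq_len(nrow(preord))) {
      par <- preord[k, 1L]; child <- preord[k, 2L]
      d <- tree$edge.length[which(tree$edge[, 1L] == par &
                                    tree$edge[, 2L] == child)]
      segAt[[child]] <- .mutateLineage(segAt[[par]], d)
    }
  })
  families <- list()
  ancestors <- list()
  for (i in seq_len(nTip)) {
    fam <- tree$tip.label[i]
    anc <- structure(list(seq = .segmentsToSeq(segAt[[i]]),
                          topology = .segmentsTopology(segAt[[i]]),
                          segments = segAt[[i]], amplified = integer(0),
                          spec = spec$barrel, seed = NA_integer_, id = fam),
                     class = "BarrelAncestor")
    fs <- familySpec(nMembers = spec$nMembers,
                     targetIdentity = spec$targetIdentity,
                     indelRate = spec$indelRate,
                     seed = deriveSeed(spec$seed, 100L + i))
    families[[fam]] <- evolveFamily(anc, fs, prefix = fam)
    ancestors[[fam]] <- anc
  }
  membership <- do.call(rbind, lapply(names(families), function(f)
    data.frame(id = names(families[[f]]), family = f,
               stringsAsFactors = FALSE)))
  list(families = families, tree = tree, membership = membership,
       ancestors = ancestors)
}

#' Random protein sequences with controlled composition
#'
#' Generates i.i.d. (non-homologous) sequences for null calibration:
#' \code{"uniform"} draws all 20 residues equally, \code{"biased"} draws
#' 70\% of residues from \{I, L, V, F\} (the strongly hydrophobic
#' composition that defeats raw-score homology detection), and
#' \code{"membrane"} uses the generator's barrel-like composition.
#'
#' @param n number of sequences.
#' @param length sequence length (single value or range).
#' @param composition one of "uniform", "biased", "membrane".
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return an \code{AAStringSet}.
#' @export
randomSeqSet <- function(n, length = 200L,
                         composition = c("uniform", "biased", "membrane"),
                         seed = 1L, prefix = "rnd") {
  composition <- match.arg(composition)
  canon <- .AA_LETTERS[1:20]
  probs <- switch(composition,
    uniform = setNames(rep(1 / 20, 20), canon),
    biased = {
      p <- setNames(rep(0.3 / 16, 20), canon)
      p[c("I", "L", "V", "F")] <- 0.7 / 4
      p
    },
    membrane = {
      p <- setNames(numeric(20), canon)
      mix <- c(.HYDRO_POOL * 0.45, .POLAR_POOL * 0.35, .LOOP_POOL * 0.20)
      for (nm in names(mix)) p[nm] <- p[nm] + mix[nm]
      p / sum(p)
    })
  withSeed(as.integer(seed), {
    lens <- if (base::length(length) == 1L) rep(length, n)
            else sample(length[1]:length[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(canon, L, replace = TRUE, prob = probs), collapse = ""),
      character(1))
    makeSeqSet(setNames(seqs, sprintf("%s%03d", prefix, seq_len(n))),
               sourceTag = sprintf("randomSeqSet(%s)", composition))
  })
}
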