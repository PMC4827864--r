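# Alignment-free family trees from all-vs-all pairwise alignment scores,
# with replicate consensus support, plus a conventional MSA-based tree
# for comparison.

#' All-vs-all local alignment scores in bits
#'
#' Computes the symmetric matrix of pairwise gapped local-alignment
#' scores for a sequence set and converts them to bits via the
#' Karlin-Altschul transform b = (lambda * S - ln K) / ln 2. Trees built
#' from this matrix need no multiple alignment.
#'
#' @param set an \code{AAStringSet} (or named character vector), at least
#'   3 sequences.
#' @param params an \code{\link{alnParams}} object.
#' @return a \code{\link{ScoreMatrix-class}} object.
#' @export
allVsAllScores <- function(set, params = alnParams()) {
  seqs <- asNamedChar(set)
  if (length(seqs) < 3L)
    stop("need at least 3 sequences", call. = FALSE)
  ka <- kaParams(params@matrixName, gapped = TRUE)
  enc <- lapply(seqs, function(s) aaEncode(normalizeSeq(s)))
  raw <- c_allpairs_scores(enc, params@matrix, params@gapOpen,
                           params@gapExtend, TRUE, FALSE)
  dimnames(raw) <- list(names(seqs), names(seqs))
  bits <- bitScore(raw, ka)
  sm <- new("ScoreMatrix", ids = names(seqs), bits = bits)
  attr(sm@bits, "raw") <- raw
  sm
}

#' Convert a bit-score matrix to distances
#'
#' d(i, j) = 1 - b(i, j) / min(b(i, i), b(j, j)), clipped to [0, 1];
#' pairs whose raw local score is non-positive saturate at d = 1. Raising
#' any off-diagonal score can only lower its distance.
#'
#' @param sm a \code{\link{ScoreMatrix-class}}.
#' @return a \code{dist} object with labels.
#' @export
scoresToDistances <- function(sm) {
  b <- sm@bits
  raw <- attr(b, "raw")
  selfs <- diag(b)
  n <- nrow(b)
  mins <- outer(selfs, selfs, pmin)
  d <- 1 - b / mins
  d[d < 0] <- 0
  d[d > 1] <- 1
  if (!is.null(raw)) d[raw <= 0] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

.fixNegBranches <- function(tr) {
  # transfer the magnitude of a negative branch to its sibling edge(s),
  # then floor at zero (path lengths approximately preserved)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    par <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == par), e)
    if (length(sibs))
      tr$edge.length[sibs] <- tr$edge.length[sibs] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}), with negative branch
#' lengths floored at zero after transferring their magnitude to the
#' sibling branch.
#'
#' @param d a \code{dist} object (or symmetric matrix) with >= 3 taxa.
#' @return an unrooted \code{phylo} object.
#' @export
njTree <- function(d) {
  m <- as.matrix(d)
  if (any(!is.finite(m)))
    stop("non-finite distances", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 taxa", call. = FALSE)
  .fixNegBranches(ape::nj(stats::as.dist(m)))
}

# Replicate distance matrices for consensus support.
#   profile: bootstrap the distance-profile coordinates (columns of the
#            protein distance matrix), an alignment-free analogue of a
#            character bootstrap
#   none:    identical replicates (useful to verify that the consensus of
#            noise-free replicates is the point-estimate tree)
.replicateDist <- function(d, strategy) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (strategy == "none") return(stats::as.dist(m))
  idx <- sample.int(n, n, replace = TRUE)
  dr <- matrix(0, n, n, dimnames = dimnames(m))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- idx[idx != i & idx != j]
      dr[i, j] <- dr[j, i] <-
        if (length(keep)) mean(abs(m[i, keep] - m[j, keep]))
        else m[i, j]
    }
  }
  stats::as.dist(dr)
}

.consensusWithSupport <- function(trees, nReplicates) {
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  pc <- ape::prop.clades(cons, trees, rooted = FALSE)
  pc[is.na(pc)] <- 0
  cons$node.label <- as.character(round(100 * pc / nReplicates))
  cons
}

#' Protein-level consensus tree from pairwise scores
#'
#' Builds \code{nReplicates} neighbor-joining trees from perturbed
#' versions of the all-vs-all score-derived distance matrix and returns
#' their majority-rule consensus with support values (percent of
#' replicates containing each bipartition). The default replicate unit is
#' a bootstrap over distance-profile coordinates; the strategy is
#' pluggable because no single resampling unit is canonical for
#' score-based trees.
#'
#' @param set an \code{AAStringSet} (>= 4 sequences).
#' @param params an \code{\link{alnParams}} object.
#' @param nReplicates number of replicate trees (default 100).
#' @param seed integer seed.
#' @param strategy \code{"profile"} (default) or \code{"none"}.
#' @param sm optional precomputed \code{\link{ScoreMatrix-class}}.
#' @return a \code{phylo} consensus tree; node labels carry support in
#'   [0, 100], \code{attr(., "pointTree")} is the unperturbed NJ tree.
#' @export
consensusTree <- function(set, params = alnParams(), nReplicates = 100L,
                          seed = 1L, strategy = c("profile", "none"),
                          sm = NULL) {
  strategy <- match.arg(strategy)
  if (length(set) < 4L) stop("need at least 4 sequences", call. = FALSE)
  if (is.null(sm)) sm <- allVsAllScores(set, params)
  d <- scoresToDistances(sm)
  point <- njTree(d)
  trees <- withSeed(as.integer(seed), {
    lapply(seq_len(nReplicates), function(r)
      njTree(.replicateDist(d, strategy)))
  })
  class(trees) <- "multiPhylo"
  cons <- .consensusWithSupport(trees, nReplicates)
  attr(cons, "pointTree") <- point
  cons
}

# Family-level distances: trimmed mean of cross-family protein distances.
.familyDistMatrix <- function(m, membersOf, trim = 0.1) {
  fams <- names(membersOf)
  k <- length(fams)
  fd <- matrix(0, k, k, dimnames = list(fams, fams))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      v <- as.vector(m[membersOf[[i]], membersOf[[j]], drop = FALSE])
      fd[i, j] <- fd[j, i] <- mean(v, trim = trim)
    }
  }
  fd
}

#' Family-level consensus tree (score-based)
#'
#' The family tree is built from trimmed-mean cross-family protein
#' distances, with consensus support from replicates that resample the
#' members of each family with replacement. Trees are only reliable when
#' each family contributes several members (at least 5 by default);
#' smaller families are kept but flagged with a warning.
#'
#' @param families named list of \code{AAStringSet}s (>= 3 families).
#' @param params an \code{\link{alnParams}} object.
#' @param minMembers warn when a family has fewer members than this.
#' @param trim trim fraction for the cross-family mean distance.
#' @param nReplicates number of member-resampling replicates.
#' @param seed integer seed.
#' @return a \code{phylo} consensus tree over families with support node
#'   labels; \code{attr(., "pointTree")} is the unperturbed NJ tree.
#' @export
familyTree <- function(families, params = alnParams(), minMembers = 5L,
                       trim = 0.1, nReplicates = 100L, seed = 1L) {
  stopifnot(is.list(families), !is.null(names(families)))
  if (length(families) < 3L) stop("need at least 3 families", call. = FALSE)
  sizes <- vapply(families, length, integer(1))
  if (any(sizes < minMembers))
    warning("families with fewer than ", minMembers, " members: ",
            paste(names(families)[sizes < minMembers], collapse = ", "),
            "; family positions may be unreliable", call. = FALSE)
  pool <- do.call(c, lapply(unname(families), as.character))
  poolSet <- makeSeqSet(pool, sourceTag = "familyTree-pool")
  sm <- allVsAllScores(poolSet, params)
  m <- as.matrix(scoresToDistances(sm))
  membersOf <- lapply(families, names)
  point <- njTree(stats::as.dist(.familyDistMatrix(m, membersOf, trim)))
  trees <- withSeed(as.integer(seed), {
    lapply(seq_len(nReplicates), function(r) {
      res <- lapply(membersOf, function(ids)
        ids[sample.int(length(ids), replace = TRUE)])
      njTree(stats::as.dist(.familyDistMatrix(m, res, trim)))
    })
  })
  class(trees) <- "multiPhylo"
  cons <- .consensusWithSupport(trees, nReplicates)
  attr(cons, "pointTree") <- point
  cons
}

# p-distances over an aligned set: mismatches / sites where both rows
# have residues; saturates at 1 when no comparable site exists.
alignmentPDist <- function(alnSet) {
  seqs <- asNamedChar(alnSet)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment", call. = FALSE)
  ch <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(ch)
  gap <- ch == "-" | ch == "."
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <-
        if (any(ok)) sum(ch[i, ok] != ch[j, ok]) / sum(ok) else 1
    }
  }
  stats::as.dist(d)
}

#' Progressive-MSA tree (conventional control)
#'
#' Aligns the set with MAFFT, computes alignment p-distances and returns
#' the neighbor-joining tree. Provided as the conventional
#' multiple-alignment route whose behaviour degrades on highly divergent
#' families, in contrast to the score-based trees.
#'
#' @param set an \code{AAStringSet} (>= 3 sequences).
#' @param params unused (kept for interface symmetry).
#' @return a \code{phylo} object; \code{attr(., "alignment")} holds the
#'   aligned \code{AAStringSet}.
#' @export
msaTree <- function(set, params = alnParams()) {
  if (length(set) < 3L) stop("need at least 3 sequences", call. = FALSE)
  aln <- mafftAlign(set)
  tr <- njTree(alignmentPDist(aln))
  attr(tr, "alignment") <- aln
  tr
}

#' Multiple alignment via MAFFT
#'
#' @param set an \code{AAStringSet} (or named character vector).
#' @return an aligned \code{AAStringSet}.
#' @export
mafftAlign <- function(set) {
  if (Sys.which("mafft") == "")
    stop("MAFFT not found on PATH; msaTree()/mafftAlign() need it",
         call. = FALSE)
  seqs <- asNamedChar(set)
  if (length(seqs) == 1L) return(makeSeqSet(seqs))
  tmp <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp, out)))
  writeFastaSet(seqs, tmp)
  status <- system2("mafft", c("--retree", "2", "--maxiterate", "0",
                               "--quiet", "--anysymbol", tmp),
                    stdout = out, stderr = FALSE)
  if (!identical(status, 0L)) stop("mafft failed", call. = FALSE)
  readFastaSet(out, aligned = TRUE, sourceTag = "mafft")
}

#' Robinson-Foulds distance between two trees
#'
#' Unweighted bipartition distance on the shared leaf set.
#'
#' @param t1,t2 \code{phylo} objects.
#' @return non-negative integer.
#' @export
rfDistance <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85")[1]
}

#' Monophyly of a grouping on an unrooted tree
#'
#' A group is monophyletic on an unrooted tree when some bipartition
#' separates exactly its members from everything else.
#'
#' @param tree a \code{phylo} object.
#' @param groups named list: group -> tip labels.
#' @return named logical vector.
#' @export
isMonophyletic <- function(tree, groups) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  all_tips <- sort(tree$tip.label)
  vapply(groups, function(tips) {
    tips <- sort(intersect(tips, all_tips))
    if (length(tips) <= 1L || length(tips) >= length(all_tips) - 1L)
      return(TRUE)
    comp <- setdiff(all_tips, tips)
    any(vapply(splits, function(s)
      identical(s, tips) || identical(s, comp), logical(1)))
  }, logical(1))
}
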