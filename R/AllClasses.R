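#' Alignment parameters
#'
#' Bundles the substitution matrix and affine gap penalties used throughout
#' the package. A gap of length g costs \code{gapOpen + (g - 1) * gapExtend}
#' (the first gapped residue pays the creation penalty). Defaults are the
#' settings used for comparison-score work on OMPP families: BLOSUM62 with
#' gap creation 8 and gap extension 2.
#'
#' @slot matrixName name of the substitution matrix.
#' @slot matrix 21 x 21 integer matrix in the package alphabet.
#' @slot gapOpen gap creation penalty (positive integer).
#' @slot gapExtend gap extension penalty (positive integer).
#' @slot endGapsFree if TRUE, leading/trailing gaps are free (semi-global).
#' @export
setClass("AlnParams",
  representation(matrixName = "character", matrix = "matrix",
                 gapOpen = "integer", gapExtend = "integer",
                 endGapsFree = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@gapOpen < object@gapExtend)
      msg <- c(msg, "gapOpen must be >= gapExtend")
    if (object@gapExtend < 1L)
      msg <- c(msg, "gapExtend must be >= 1")
    if (!isTRUE(all.equal(object@matrix, t(object@matrix))))
      msg <- c(msg, "substitution matrix must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' @describeIn AlnParams constructor.
#' @param matrixName,gapOpen,gapExtend,endGapsFree see slots.
#' @export
alnParams <- function(matrixName = "BLOSUM62", gapOpen = 8L, gapExtend = 2L,
                      endGapsFree = FALSE) {
  new("AlnParams", matrixName = matrixName,
      matrix = getSubMatrix(matrixName),
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      endGapsFree = endGapsFree)
}

setMethod("show", "AlnParams", function(object) {
  cat("AlnParams:", object@matrixName,
      sprintf("gap %d/%d%s\n", object@gapOpen, object@gapExtend,
              if (object@endGapsFree) " (end gaps free)" else ""))
})

#' Pairwise alignment result
#'
#' @slot idA,idB sequence identifiers (may be empty strings).
#' @slot alignedA,alignedB equal-length gapped strings.
#' @slot score optimal alignment score (integer-valued).
#' @slot percentIdentity percent of alignment columns with identical
#'   residues.
#' @slot percentSimilarity percent of alignment columns whose residue pair
#'   is identical or scores > 0 in the substitution matrix.
#' @slot spanA,spanB 1-based inclusive start/end of the aligned region on
#'   each unaligned sequence (length-2 integer; c(0, -1) for an empty
#'   local alignment).
#' @slot local TRUE for Smith-Waterman local alignments.
#' @export
setClass("PairAln",
  representation(idA = "character", idB = "character",
                 alignedA = "character", alignedB = "character",
                 score = "numeric", percentIdentity = "numeric",
                 percentSimilarity = "numeric",
                 spanA = "integer", spanB = "integer", local = "logical"),
  validity = function(object) {
    if (nchar(object@alignedA) != nchar(object@alignedB))
      return("gapped strings must have equal length")
    TRUE
  })

setMethod("show", "PairAln", function(object) {
  cat(sprintf("%s alignment %s vs %s\n",
              if (object@local) "Local" else "Global",
              if (nzchar(object@idA)) object@idA else "seqA",
              if (nzchar(object@idB)) object@idB else "seqB"))
  cat(sprintf("  score %g, identity %.1f%%, similarity %.1f%%, spans %d-%d / %d-%d\n",
              object@score, object@percentIdentity, object@percentSimilarity,
              object@spanA[1], object@spanA[2],
              object@spanB[1], object@spanB[2]))
})

#' Shuffle-null comparison score
#'
#' The global alignment score of two sequences expressed in standard
#' deviations of a Monte-Carlo null distribution obtained by re-aligning
#' residue-shuffled copies of the sequences. Scores of this kind correct
#' for the biased residue compositions typical of integral membrane
#' proteins; a value of at least 12 SD over a comparable segment of at
#' least 60 residues is the package's default evidence threshold for
#' homology.
#'
#' @slot zSD the comparison score in standard-deviation units
#'   (NA when the null is degenerate).
#' @slot observedScore global alignment score of the native sequences.
#' @slot nullMean,nullSD mean and sample SD of the shuffled-score null.
#' @slot nShuffles number of shuffles.
#' @slot seed integer seed used for the shuffles.
#' @slot degenerate TRUE when the null SD is zero (e.g. homopolymers).
#' @export
setClass("ShuffleZ",
  representation(zSD = "numeric", observedScore = "numeric",
                 nullMean = "numeric", nullSD = "numeric",
                 nShuffles = "integer", seed = "integer",
                 degenerate = "logical"),
  validity = function(object) {
    if (object@nShuffles < 2L) return("need at least 2 shuffles")
    if (!object@degenerate && object@nullSD <= 0)
      return("nullSD must be > 0 unless flagged degenerate")
    TRUE
  })

setMethod("show", "ShuffleZ", function(object) {
  if (object@degenerate) {
    cat("Comparison score: undefined (degenerate null, SD = 0)\n")
  } else {
    cat(sprintf("Comparison score: %.1f SD (observed %g, null %.1f +/- %.2f, %d shuffles)\n",
                object@zSD, object@observedScore, object@nullMean,
                object@nullSD, object@nShuffles))
  }
})

#' Comparable-segment rule
#'
#' Evidence rule for homology: a comparison score threshold (in SD) that
#' must be reached over a comparable segment of a minimum number of
#' residues in each protein.
#'
#' @slot minLength minimum de-gapped segment length (default 60 residues,
#'   the size of a prototypical protein domain).
#' @slot sdThreshold comparison-score threshold in SD (default 12).
#' @export
setClass("SegmentRule",
  representation(minLength = "integer", sdThreshold = "numeric"),
  validity = function(object)
    if (object@minLength < 1L) "minLength must be >= 1" else TRUE)

#' @describeIn SegmentRule constructor.
#' @param minLength,sdThreshold see slots.
#' @export
segmentRule <- function(minLength = 60L, sdThreshold = 12.0) {
  new("SegmentRule", minLength = as.integer(minLength),
      sdThreshold = sdThreshold)
}

#' Transitive homology chain
#'
#' An A-B-C-D chain of pairwise comparisons. The chain is accepted when
#' every link exceeds the SD threshold over a comparable segment of at
#' least the minimum length, or when the direct A-D comparison alone meets
#' the threshold (in which case the bridge comparisons are unnecessary).
#'
#' @slot ids identifiers of the chain members, in order.
#' @slot linkZ comparison scores (SD) for consecutive links.
#' @slot linkSegLen comparable-segment lengths (residues, the shorter of
#'   the two de-gapped segments) for consecutive links.
#' @slot directZ direct A-vs-D comparison score, or NA if not computed.
#' @slot directSegLen comparable-segment length for the direct comparison.
#' @slot accepted TRUE when the chain establishes homology.
#' @slot method "direct" or "chained".
#' @slot reason free-text note (e.g. rejection reason).
#' @export
setClass("HomologyChain",
  representation(ids = "character", linkZ = "numeric",
                 linkSegLen = "integer", directZ = "numeric",
                 directSegLen = "integer", accepted = "logical",
                 method = "character", reason = "character"))

setMethod("show", "HomologyChain", function(object) {
  cat("Homology chain:", paste(object@ids, collapse = " - "), "\n")
  if (length(object@linkZ))
    cat("  link scores (SD):",
        paste(sprintf("%.1f", object@linkZ), collapse = ", "), "\n")
  if (!is.na(object@directZ))
    cat(sprintf("  direct %s vs %s: %.1f SD\n", object@ids[1],
                object@ids[length(object@ids)], object@directZ))
  cat("  accepted:", object@accepted,
      if (nzchar(object@reason)) paste0(" (", object@reason, ")") else "",
      "\n", sep = "")
})

#' Superfamily assignment
#'
#' Connected components of the accepted-evidence graph over families.
#' Components are labelled SF1, SF2, ... in decreasing size order.
#' Families with no accepted evidence carry status "no evidence": absence
#' of demonstrated homology never asserts non-membership.
#'
#' @slot familyComponent named character vector: family -> superfamily
#'   label (singletons with no evidence get their own label).
#' @slot members list: superfamily label -> character vector of families.
#' @slot evidence data.frame of accepted family-pair evidence
#'   (familyA, familyB, z, method).
#' @slot status named character vector: family -> "assigned" or
#'   "no evidence".
#' @export
setClass("SuperfamilyAssignment",
  representation(familyComponent = "character", members = "list",
                 evidence = "data.frame", status = "character"))

setMethod("show", "SuperfamilyAssignment", function(object) {
  sizes <- vapply(object@members, length, integer(1))
  cat("Superfamily assignment:", length(object@familyComponent),
      "families in", length(object@members), "components\n")
  multi <- sizes[sizes > 1]
  if (length(multi))
    for (nm in names(multi))
      cat(" ", nm, ":", paste(object@members[[nm]], collapse = ", "), "\n")
  n_no <- sum(object@status == "no evidence")
  if (n_no) cat(" ", n_no, "family/ies with no evidence (unassigned)\n")
})

#' All-vs-all bit-score matrix
#'
#' @slot ids sequence identifiers.
#' @slot bits symmetric matrix of pairwise local-alignment scores in bits.
#' @export
setClass("ScoreMatrix",
  representation(ids = "character", bits = "matrix"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@bits, t(object@bits), tolerance = 1e-8)))
      return("bit-score matrix must be symmetric")
    TRUE
  })

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix:", length(object@ids), "sequences, bit scores in [",
      sprintf("%.1f, %.1f", min(object@bits), max(object@bits)), "]\n")
})

#' Predicted beta-strand topology
#'
#' @slot strands \link[IRanges]{IRanges} of transmembrane beta-strand
#'   intervals (1-based inclusive, on the ungapped sequence).
#' @slot nStrands number of strands.
#' @slot caller name of the calling method.
#' @export
setClass("BetaTopology",
  representation(strands = "IRanges", nStrands = "integer",
                 caller = "character"),
  validity = function(object) {
    s <- object@strands
    if (length(s) != object@nStrands) return("nStrands mismatch")
    if (length(s) > 1) {
      if (is.unsorted(IRanges::start(s)))
        return("strand intervals must be sorted")
      if (any(IRanges::start(s)[-1] <= IRanges::end(s)[-length(s)]))
        return("strand intervals must not overlap")
    }
    TRUE
  })

setMethod("show", "BetaTopology", function(object) {
  cat("BetaTopology:", object@nStrands, "strand(s) [", object@caller, "]\n")
  if (object@nStrands > 0) {
    iv <- sprintf("%d-%d", IRanges::start(object@strands),
                  IRanges::end(object@strands))
    cat(" ", paste(iv, collapse = ", "), "\n")
  }
})

#' @rdname BetaTopology-class
#' @param strands an \code{IRanges} of strand intervals.
#' @param caller caller name.
#' @export
BetaTopology <- function(strands, caller = "manual") {
  strands <- strands[order(IRanges::start(strands))]
  new("BetaTopology", strands = strands,
      nStrands = length(strands), caller = caller)
}

# ---- simple accessors (Bioconductor style: no direct slot access) ----

#' Accessors for ompbarrel result objects
#'
#' Small generics that extract the headline quantities from result
#' objects: \code{zSD} (comparison score in SD), \code{alnScore} (raw
#' alignment score), \code{isAccepted} (homology decision),
#' \code{strandRanges} / \code{nStrands} (strand topology),
#' \code{percentIdentity} / \code{percentSimilarity} (alignment column
#' statistics) and \code{superfamilyOf} (family-to-superfamily map).
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("zSD", function(x) standardGeneric("zSD"))
#' @rdname accessors
#' @export
setMethod("zSD", "ShuffleZ", function(x) x@zSD)
#' @rdname accessors
#' @export
setMethod("zSD", "HomologyChain", function(x) x@linkZ)

#' @rdname accessors
#' @export
setGeneric("alnScore", function(x) standardGeneric("alnScore"))
#' @rdname accessors
#' @export
setMethod("alnScore", "PairAln", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("alnScore", "ShuffleZ", function(x) x@observedScore)

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setMethod("isAccepted", "HomologyChain", function(x) x@accepted)

#' @rdname accessors
#' @export
setGeneric("strandRanges", function(x) standardGeneric("strandRanges"))
#' @rdname accessors
#' @export
setMethod("strandRanges", "BetaTopology", function(x) x@strands)

#' @rdname accessors
#' @export
setGeneric("nStrands", function(x) standardGeneric("nStrands"))
#' @rdname accessors
#' @export
setMethod("nStrands", "BetaTopology", function(x) x@nStrands)

#' @rdname accessors
#' @export
setGeneric("percentIdentity", function(x) standardGeneric("percentIdentity"))
#' @rdname accessors
#' @export
setMethod("percentIdentity", "PairAln", function(x) x@percentIdentity)

#' @rdname accessors
#' @export
setGeneric("percentSimilarity",
           function(x) standardGeneric("percentSimilarity"))
#' @rdname accessors
#' @export
setMethod("percentSimilarity", "PairAln", function(x) x@percentSimilarity)

#' @rdname accessors
#' @export
setGeneric("superfamilyOf", function(x) standardGeneric("superfamilyOf"))
#' @rdname accessors
#' @export
setMethod("superfamilyOf", "SuperfamilyAssignment",
          function(x) x@familyComponent)
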