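#' Monte-Carlo shuffle-null comparison score
#'
#' Computes the comparison score of two sequences in standard-deviation
#' units: the optimal global alignment score of the native sequences,
#' centred and scaled by the mean and sample SD of the scores obtained
#' after independently shuffling the residues of each sequence (2000
#' shuffles by default). Because every shuffled replicate preserves both
#' residue compositions exactly, the statistic is calibrated even for the
#' biased compositions of integral membrane proteins, where raw alignment
#' scores are not.
#'
#' @param a,b sequences (character, \code{AAString} or single-element
#'   \code{AAStringSet}), each at least 2 residues.
#' @param params an \code{\link{alnParams}} object.
#' @param nShuffles number of shuffled replicates (default 2000).
#' @param seed integer seed; if NULL one is drawn from the session RNG and
#'   recorded in the result.
#' @param shuffleBoth shuffle both sequences per replicate (default), or
#'   only the first.
#' @param local use local instead of global alignment (used for short
#'   repeat-unit comparisons).
#' @return a \code{\link{ShuffleZ-class}} object. When the null SD is zero
#'   (e.g. homopolymers) the result is flagged degenerate and \code{zSD}
#'   is NA rather than an error.
#' @examples
#' s <- paste(rep("ACDEFGHIKL", 10), collapse = "")
#' shuffleZ(s, s, nShuffles = 100, seed = 1)
#' @export
shuffleZ <- function(a, b, params = alnParams(), nShuffles = 2000L,
                     seed = NULL, shuffleBoth = TRUE, local = FALSE) {
  a <- normalizeSeq(asSeqChar(a)); b <- normalizeSeq(asSeqChar(b))
  if (nchar(a) < 2L || nchar(b) < 2L)
    stop("sequences must have at least 2 residues", call. = FALSE)
  nShuffles <- as.integer(nShuffles)
  if (nShuffles < 2L) stop("need at least 2 shuffles", call. = FALSE)
  if (is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  seed <- as.integer(seed)
  ea <- aaEncode(a); eb <- aaEncode(b)
  obs <- c_align_score(ea, eb, params@matrix, params@gapOpen,
                       params@gapExtend, local, params@endGapsFree)
  null <- withSeed(seed, c_shuffle_null(ea, eb, params@matrix, params@gapOpen,
                                        params@gapExtend, nShuffles,
                                        shuffleBoth, local,
                                        params@endGapsFree))
  mu <- mean(null)
  sdv <- sd(null)
  degenerate <- !is.finite(sdv) || sdv == 0
  new("ShuffleZ",
      zSD = if (degenerate) NA_real_ else (obs - mu) / sdv,
      observedScore = obs, nullMean = mu,
      nullSD = if (degenerate) 0 else sdv,
      nShuffles = nShuffles, seed = seed, degenerate = degenerate)
}

#' Comparison score on the comparable segment of two proteins
#'
#' Convenience wrapper implementing the full evidence protocol for one
#' pair: globally align, trim the alignment ends to the comparable segment
#' (at least \code{rule@minLength} residues per protein, maximizing
#' identities and minimizing gaps), then compute \code{\link{shuffleZ}} on
#' the trimmed contiguous substrings.
#'
#' @inheritParams shuffleZ
#' @param rule a \code{\link{segmentRule}}.
#' @return list with \code{z} (a \code{ShuffleZ} or NULL when no
#'   qualifying segment exists), \code{segment} (see
#'   \code{\link{extractComparableSegment}}), \code{segLen} (shorter
#'   de-gapped segment length, 0 when none) and \code{pass} (TRUE when
#'   the score meets \code{rule@sdThreshold} on a qualifying segment).
#' @export
segmentShuffleZ <- function(a, b, params = alnParams(), rule = segmentRule(),
                            nShuffles = 2000L, seed = NULL,
                            strict = TRUE) {
  a <- normalizeSeq(asSeqChar(a)); b <- normalizeSeq(asSeqChar(b))
  if (min(nchar(a), nchar(b)) < rule@minLength)
    return(list(z = NULL, segment = NULL, segLen = 0L, pass = FALSE,
                reason = sprintf("sequence below %d aa", rule@minLength)))
  aln <- globalAlign(a, b, params)
  seg <- extractComparableSegment(aln, rule)
  if (is.null(seg))
    return(list(z = NULL, segment = NULL, segLen = 0L, pass = FALSE,
                reason = "no comparable segment"))
  z <- shuffleZ(seg$segA, seg$segB, params, nShuffles = nShuffles,
                seed = seed)
  segLen <- min(nchar(seg$segA), nchar(seg$segB))
  pass <- !z@degenerate &&
    (if (strict) z@zSD > rule@sdThreshold else z@zSD >= rule@sdThreshold)
  list(z = z, segment = seg, segLen = as.integer(segLen), pass = pass,
       reason = "")
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a bounded child seed from a master seed and a stream index
# (kept below 2^31 so it is always a valid R integer).
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483587)
}
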