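# Pairwise alignment front-end over the compiled Gotoh engine.

.buildPairAln <- function(a, b, idA, idB, tb, params, local) {
  chA <- strsplit(a, "")[[1L]]
  chB <- strsplit(b, "")[[1L]]
  ga <- ifelse(is.na(tb$ia), "-", chA[tb$ia])
  gb <- ifelse(is.na(tb$ib), "-", chB[tb$ib])
  L <- length(ga)
  if (L > 0L) {
    both <- !is.na(tb$ia) & !is.na(tb$ib)
    ident <- both & ga == gb
    sm <- params@matrix
    pos <- logical(L)
    if (any(both))
      pos[both] <- sm[cbind(ga[both], gb[both])] > 0L
    pid <- 100 * sum(ident) / L
    psim <- 100 * sum(ident | (both & pos)) / L
    ia <- tb$ia[!is.na(tb$ia)]
    ib <- tb$ib[!is.na(tb$ib)]
    spanA <- c(min(ia), max(ia))
    spanB <- c(min(ib), max(ib))
  } else {
    pid <- psim <- 0
    spanA <- spanB <- c(0L, -1L)
  }
  new("PairAln", idA = idA, idB = idB,
      alignedA = paste(ga, collapse = ""), alignedB = paste(gb, collapse = ""),
      score = tb$score, percentIdentity = pid, percentSimilarity = psim,
      spanA = as.integer(spanA), spanB = as.integer(spanB), local = local)
}

#' Optimal global (Needleman-Wunsch) alignment
#'
#' Affine gap penalties with the GCG convention (a gap of length g costs
#' \code{gapOpen + (g-1) * gapExtend}); end gaps are penalized unless the
#' parameters free them. Traceback is deterministic (at ties: match state,
#' then gap in the second sequence, then gap in the first).
#'
#' @param a,b sequences (character, \code{AAString}, or single-element
#'   \code{AAStringSet}).
#' @param params an \code{\link{alnParams}} object.
#' @param idA,idB optional identifiers carried into the result.
#' @return a \code{\link{PairAln-class}} object.
#' @examples
#' globalAlign("ACDEFGHIKL", "ACDEFGHIKL")
#' @export
globalAlign <- function(a, b, params = alnParams(), idA = "", idB = "") {
  a <- normalizeSeq(asSeqChar(a)); b <- normalizeSeq(asSeqChar(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  tb <- c_align_traceback(aaEncode(a), aaEncode(b), params@matrix,
                          params@gapOpen, params@gapExtend, FALSE,
                          params@endGapsFree)
  .buildPairAln(a, b, idA, idB, tb, params, local = FALSE)
}

#' Optimal local (Smith-Waterman) alignment
#'
#' As \code{\link{globalAlign}} but local; when no positive-scoring
#' residue pair exists the alignment is empty with score 0.
#'
#' @inheritParams globalAlign
#' @return a \code{\link{PairAln-class}} object.
#' @export
localAlign <- function(a, b, params = alnParams(), idA = "", idB = "") {
  a <- normalizeSeq(asSeqChar(a)); b <- normalizeSeq(asSeqChar(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  tb <- c_align_traceback(aaEncode(a), aaEncode(b), params@matrix,
                          params@gapOpen, params@gapExtend, TRUE, FALSE)
  .buildPairAln(a, b, idA, idB, tb, params, local = TRUE)
}

# Fast score-only entry points used by the screens and the simulator.
alignScoreOnly <- function(a, b, params = alnParams(), local = FALSE) {
  c_align_score(aaEncode(normalizeSeq(asSeqChar(a))),
                aaEncode(normalizeSeq(asSeqChar(b))),
                params@matrix, params@gapOpen, params@gapExtend,
                local, params@endGapsFree)
}

#' Text alignment report
#'
#' Writes a pairwise alignment in 60-column blocks with \code{|} marking
#' identities, \code{:} marking similarities (substitution score > 0) and
#' residue numbers at line ends.
#'
#' @param aln a \code{\link{PairAln-class}} object.
#' @param params alignment parameters (for the similarity marks).
#' @param file connection or file name (\code{""} prints to stdout).
#' @param blockWidth characters per block.
#' @return invisibly, the report lines.
#' @export
writeAlignmentReport <- function(aln, params = alnParams(), file = "",
                                 blockWidth = 60L) {
  ga <- strsplit(aln@alignedA, "")[[1L]]
  gb <- strsplit(aln@alignedB, "")[[1L]]
  L <- length(ga)
  marks <- character(L)
  both <- ga != "-" & gb != "-"
  marks[!both] <- " "
  marks[both & ga == gb] <- "|"
  simi <- both & ga != gb & params@matrix[cbind(
    ifelse(both, ga, "X"), ifelse(both, gb, "X"))] > 0L
  marks[simi] <- ":"
  marks[both & ga != gb & !simi] <- " "
  posA <- cumsum(ga != "-") + max(0L, aln@spanA[1L] - 1L)
  posB <- cumsum(gb != "-") + max(0L, aln@spanB[1L] - 1L)
  out <- c(sprintf("# %s vs %s  score %g  identity %.1f%%  similarity %.1f%%",
                   ifelse(nzchar(aln@idA), aln@idA, "seqA"),
                   ifelse(nzchar(aln@idB), aln@idB, "seqB"),
                   aln@score, aln@percentIdentity, aln@percentSimilarity))
  starts <- seq(1L, max(L, 1L), by = blockWidth)
  for (s in starts) {
    e <- min(s + blockWidth - 1L, L)
    if (e < s) break
    out <- c(out,
             sprintf("%6d %s %d", if (any(ga[s:e] != "-")) posA[s:e][ga[s:e] != "-"][1L] else posA[s],
                     paste(ga[s:e], collapse = ""), posA[e]),
             sprintf("%6s %s", "", paste(marks[s:e], collapse = "")),
             sprintf("%6d %s %d", if (any(gb[s:e] != "-")) posB[s:e][gb[s:e] != "-"][1L] else posB[s],
                     paste(gb[s:e], collapse = ""), posB[e]),
             "")
  }
  writeLines(out, con = if (identical(file, "")) stdout() else file)
  invisible(out)
}

#' Extract the comparable segment of an alignment
#'
#' Trims alignment columns from the two ends only, choosing the contiguous
#' column window that maximizes (identities - gapped columns) subject to
#' both de-gapped segments retaining at least \code{minLength} residues.
#' Central regions are never removed: the returned segments are contiguous
#' substrings of the input sequences. Ties favour the leftmost, then
#' widest window.
#'
#' @param aln a \code{\link{PairAln-class}} object.
#' @param rule a \code{\link{segmentRule}} (minimum length; the SD
#'   threshold is not used here).
#' @return \code{NULL} when no qualifying trim exists, else a list with
#'   \code{segA}, \code{segB} (contiguous de-gapped substrings),
#'   \code{spanA}, \code{spanB} (1-based inclusive coordinates on the
#'   unaligned sequences), \code{columns} (retained alignment columns) and
#'   \code{value} (the trimming objective).
#' @export
extractComparableSegment <- function(aln, rule = segmentRule()) {
  ga <- strsplit(aln@alignedA, "")[[1L]]
  gb <- strsplit(aln@alignedB, "")[[1L]]
  L <- length(ga)
  if (L == 0L) return(NULL)
  gapcol <- ga == "-" | gb == "-"
  identcol <- !gapcol & ga == gb
  v <- ifelse(identcol, 1L, ifelse(gapcol, -1L, 0L))
  cv <- c(0L, cumsum(v))
  cntA <- c(0L, cumsum(ga != "-"))
  cntB <- c(0L, cumsum(gb != "-"))
  minL <- rule@minLength
  best <- NULL
  bestVal <- -Inf
  for (l in seq_len(L)) {
    r <- l:L
    okA <- (cntA[r + 1L] - cntA[l]) >= minL
    okB <- (cntB[r + 1L] - cntB[l]) >= minL
    ok <- okA & okB
    if (!any(ok)) next
    vals <- cv[r + 1L] - cv[l]
    vals[!ok] <- -Inf
    m <- max(vals)
    if (m > bestVal) {                       # leftmost l wins ties
      ri <- which(vals == m)
      bestVal <- m
      best <- c(l, r[ri[length(ri)]])        # widest r among equal values
    }
  }
  if (is.null(best)) return(NULL)
  l <- best[1L]; r <- best[2L]
  idxA <- which(ga != "-")
  idxB <- which(gb != "-")
  inA <- idxA[idxA >= l & idxA <= r]
  inB <- idxB[idxB >= l & idxB <= r]
  # residue coordinates on the unaligned inputs
  rankA <- cumsum(ga != "-")
  rankB <- cumsum(gb != "-")
  offA <- max(0L, aln@spanA[1L] - 1L)
  offB <- max(0L, aln@spanB[1L] - 1L)
  spanA <- c(rankA[inA[1L]], rankA[inA[length(inA)]]) + offA
  spanB <- c(rankB[inB[1L]], rankB[inB[length(inB)]]) + offB
  list(segA = paste(ga[inA], collapse = ""),
       segB = paste(gb[inB], collapse = ""),
       spanA = as.integer(spanA), spanB = as.integer(spanB),
       columns = c(l, r), value = bestVal)
}
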