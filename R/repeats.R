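# Intra-protein beta-hairpin repeat scan: compare candidate hairpin
# units within one protein using the shuffle-null statistic.

#' Enumerate beta-hairpin units from a strand topology
#'
#' A hairpin unit spans strand k through strand k+1 including the
#' connecting turn. The default "disjoint" mode pairs strands
#' (1,2), (3,4), ... (the tandem-hairpin model of barrel growth);
#' "sliding" mode emits every consecutive pair.
#'
#' @param topology a \code{\link{BetaTopology-class}} with >= 2 strands.
#' @param seq the protein sequence the topology refers to.
#' @param mode \code{"disjoint"} (default) or \code{"sliding"}.
#' @param minUnitLen drop units shorter than this (default 12 residues).
#' @return data.frame (unit, strand1, strand2, start, end, seq); empty
#'   with zero rows when fewer than two strands.
#' @export
enumerateHairpins <- function(topology, seq, mode = c("disjoint", "sliding"),
                              minUnitLen = 12L) {
  mode <- match.arg(mode)
  s <- normalizeSeq(asSeqChar(seq))
  ns <- nStrands(topology)
  empty <- data.frame(unit = integer(0), strand1 = integer(0),
                      strand2 = integer(0), start = integer(0),
                      end = integer(0), seq = character(0))
  if (ns < 2L) return(empty)
  first <- if (mode == "disjoint") seq(1L, ns - 1L, by = 2L)
           else seq_len(ns - 1L)
  st <- IRanges::start(strandRanges(topology))
  en <- IRanges::end(strandRanges(topology))
  out <- data.frame(unit = seq_along(first), strand1 = first,
                    strand2 = first + 1L, start = st[first],
                    end = en[first + 1L])
  out$seq <- substring(s, out$start, out$end)
  out <- out[nchar(out$seq) >= minUnitLen, , drop = FALSE]
  out$unit <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scan a protein for internal hairpin repeats
#'
#' Compares every pair of hairpin units with a shuffle-null statistic:
#' units are locally aligned (short segments, so a reduced gap-opening
#' penalty is used) and the observed score is referred to the score
#' distribution of residue-shuffled unit copies, yielding a z value in SD
#' and an empirical P value \code{(1 + #\{null >= observed\}) /
#' (nShuffles + 1)}. Units are shorter than the 60-residue evidence rule,
#' so hits quantify repeat similarity but are never labelled established
#' homology.
#'
#' @param seq protein sequence.
#' @param topology a \code{\link{BetaTopology-class}} for the sequence
#'   (e.g. from \code{\link{predictBetaTms}} or simulator ground truth).
#' @param params alignment parameters for unit comparison (default:
#'   BLOSUM62 with gap open 4, extend 2).
#' @param nShuffles shuffles per unit pair (default 2000).
#' @param seed master seed.
#' @param mode hairpin pairing mode, see \code{\link{enumerateHairpins}}.
#' @return data.frame sorted by decreasing z: unitA, unitB, startA, endA,
#'   startB, endB, score, z, empiricalP.
#' @export
hairpinRepeatScan <- function(seq, topology,
                              params = alnParams(gapOpen = 4L,
                                                 gapExtend = 2L),
                              nShuffles = 2000L, seed = 1L,
                              mode = "disjoint") {
  s <- normalizeSeq(asSeqChar(seq))
  units <- enumerateHairpins(topology, s, mode = mode)
  empty <- data.frame(unitA = integer(0), unitB = integer(0),
                      startA = integer(0), endA = integer(0),
                      startB = integer(0), endB = integer(0),
                      score = numeric(0), z = numeric(0),
                      empiricalP = numeric(0))
  if (nrow(units) < 2L) return(empty)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(units) - 1L)) {
    for (j in (i + 1L):nrow(units)) {
      k <- k + 1L
      ua <- units$seq[i]; ub <- units$seq[j]
      obs <- alignScoreOnly(ua, ub, params, local = TRUE)
      null <- withSeed(deriveSeed(seed, 1000L + i * 101L + j), {
        c_shuffle_null(aaEncode(ua), aaEncode(ub), params@matrix,
                       params@gapOpen, params@gapExtend,
                       as.integer(nShuffles), TRUE, TRUE, FALSE)
      })
      mu <- mean(null); sdv <- sd(null)
      rows[[k]] <- data.frame(
        unitA = units$unit[i], unitB = units$unit[j],
        startA = units$start[i], endA = units$end[i],
        startB = units$start[j], endB = units$end[j],
        score = obs,
        z = if (is.finite(sdv) && sdv > 0) (obs - mu) / sdv else NA_real_,
        empiricalP = (1 + sum(null >= obs)) / (nShuffles + 1))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$z, out$unitA, out$unitB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a repeat-scan report
#'
#' @param hits output of \code{\link{hairpinRepeatScan}}.
#' @param id protein identifier for the report.
#' @param path TSV path.
#' @export
writeRepeatReport <- function(hits, id, path) {
  hits$id <- id
  write.table(hits[, c("id", setdiff(names(hits), "id"))], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
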