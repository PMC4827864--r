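# Average hydropathy / amphipathicity / similarity profiles over family
# alignments, and a simple transmembrane beta-strand caller.

#' Hydropathy scale
#'
#' @param name currently \code{"KD"} (Kyte-Doolittle).
#' @return named numeric vector over the 21-letter package alphabet
#'   (X = 0).
#' @export
hydropathyScale <- function(name = "KD") {
  if (name != "KD") stop("unknown hydropathy scale: ", name, call. = FALSE)
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3, X = 0)
}

# Centered moving average with shrinking windows at the edges.
.winMean <- function(v, window) {
  n <- length(v)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(v[lo:hi])
  }
  out
}

# Windowed hydrophobic moment (Eisenberg) at periodicity angle `angle`
# (degrees): mu_i = |sum_k h_k exp(i * delta * k)| / W over the window
# centred at i. 180 degrees probes beta-strand periodicity, ~100 degrees
# alpha-helical periodicity.
.winMoment <- function(h, window, angle) {
  n <- length(h)
  half <- window %/% 2L
  delta <- angle * pi / 180
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    k <- lo:hi
    out[i] <- sqrt(sum(h[k] * sin(delta * k))^2 +
                   sum(h[k] * cos(delta * k))^2) / length(k)
  }
  out
}

#' Average hydropathy / amphipathicity / similarity profile
#'
#' Column-wise profile over a family multiple alignment: mean windowed
#' hydropathy of the non-gap residues, mean windowed hydrophobic moment
#' at the chosen periodicity angle, and column conservation (1 minus the
#' normalized Shannon entropy of the residue distribution). Windowed
#' values are computed per sequence on its ungapped residues and mapped
#' back to alignment columns, so gaps never dilute the windows.
#'
#' @param msa an aligned \code{AAStringSet} (equal widths) or character
#'   vector.
#' @param window odd window size (default 9).
#' @param angle periodicity angle in degrees (default 180 for
#'   beta-strands; ~100 probes alpha-helices).
#' @param scale hydropathy scale from \code{\link{hydropathyScale}}.
#' @return a \code{DataFrame} with one row per alignment column:
#'   \code{column}, \code{hydropathy}, \code{amphipathicity},
#'   \code{similarity}, \code{occupancy} (fraction of rows with a
#'   residue).
#' @export
avehasProfile <- function(msa, window = 9L, angle = 180,
                          scale = hydropathyScale("KD")) {
  seqs <- toupper(asNamedChar(msa))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment", call. = FALSE)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  ch <- do.call(rbind, strsplit(seqs, ""))
  ch[ch == "."] <- "-"
  ch[!(ch %in% c(names(scale), "-"))] <- "X"
  n <- nrow(ch)
  hyd <- matrix(NA_real_, n, L)
  amp <- matrix(NA_real_, n, L)
  for (r in seq_len(n)) {
    res <- which(ch[r, ] != "-")
    if (!length(res)) next
    h <- unname(scale[ch[r, res]])
    hyd[r, res] <- .winMean(h, window)
    amp[r, res] <- .winMoment(h, window, angle)
  }
  occ <- colSums(ch != "-") / n
  sim <- vapply(seq_len(L), function(j) {
    col <- ch[, j]
    col <- col[col != "-"]
    if (!length(col)) return(0)
    p <- table(col) / length(col)
    1 - (-sum(p * log(p))) / log(20)
  }, numeric(1))
  S4Vectors::DataFrame(
    column = seq_len(L),
    hydropathy = colMeans(hyd, na.rm = TRUE),
    amphipathicity = colMeans(amp, na.rm = TRUE),
    similarity = sim,
    occupancy = occ)
}

# Strand-propensity score per residue: beta-periodicity amphipathic
# moment plus the positive part of the windowed hydropathy. The primary
# threshold and the hysteresis extension factor were calibrated once on
# the synthetic barrel generator (50 barrels spanning 4-14 hairpins) and
# are held fixed thereafter.
.BETA_TMS_THRESHOLD <- 1.3
.BETA_TMS_EXTEND <- 0.3
.BETA_TMS_WINDOW <- 5L

.strandScores <- function(h, window = .BETA_TMS_WINDOW) {
  .winMoment(h, window, 180) + pmax(0, .winMean(h, window))
}

# Greedy maximal non-overlapping window selection over candidate strand
# windows of length minLen..maxLen whose mean score clears the threshold,
# followed by hysteresis extension: an accepted call grows outward while
# the neighbouring per-residue score stays above extend * threshold (up
# to maxLen, respecting the minimum separation between calls).
.callStrands <- function(score, minLen, maxLen, threshold,
                         extend = .BETA_TMS_EXTEND, minSep = 2L) {
  n <- length(score)
  if (n < minLen) return(IRanges::IRanges())
  cs <- c(0, cumsum(score))
  cand <- do.call(rbind, lapply(minLen:maxLen, function(L) {
    if (n < L) return(NULL)
    s <- seq_len(n - L + 1L)
    mu <- (cs[s + L] - cs[s]) / L
    cbind(start = s, end = s + L - 1L, mean = mu)
  }))
  cand <- cand[cand[, "mean"] >= threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(IRanges::IRanges())
  # deterministic greedy: best mean, then longest, then leftmost
  cand <- cand[order(-cand[, "mean"],
                     -(cand[, "end"] - cand[, "start"]),
                     cand[, "start"]), , drop = FALSE]
  taken <- logical(n)
  keep <- list()
  ext <- extend * threshold
  for (k in seq_len(nrow(cand))) {
    s <- cand[k, "start"]; e <- cand[k, "end"]
    lo <- max(1L, s - minSep); hi <- min(n, e + minSep)
    if (any(taken[lo:hi])) next
    # symmetric hysteresis: repeatedly extend towards the higher-scoring
    # free neighbour, so calls mirror under sequence reversal
    repeat {
      if ((e - s + 1L) >= maxLen) break
      canL <- s > 1L && score[s - 1L] >= ext &&
        !any(taken[max(1L, s - 1L - minSep):(s - 1L)])
      canR <- e < n && score[e + 1L] >= ext &&
        !any(taken[(e + 1L):min(n, e + 1L + minSep)])
      if (!canL && !canR) break
      if (canL && (!canR || score[s - 1L] >= score[e + 1L]))
        s <- s - 1L
      else
        e <- e + 1L
    }
    taken[s:e] <- TRUE
    keep[[length(keep) + 1L]] <- c(s, e)
  }
  if (!length(keep)) return(IRanges::IRanges())
  mat <- do.call(rbind, keep)
  IRanges::IRanges(start = mat[, 1L], end = mat[, 2L])
}

#' Predict transmembrane beta-strands
#'
#' Simple deterministic strand caller: per-residue score = windowed
#' hydrophobic moment at 180 degrees plus the positive part of the
#' windowed hydropathy; maximal non-overlapping windows of length
#' \code{minLen}..\code{maxLen} whose mean score clears a fixed threshold
#' are reported as strands. Single-sequence strand prediction is
#' intrinsically noisy; averaging over family members (see
#' \code{\link{countTmsByFamily}}) is the recommended use.
#'
#' @param x a sequence (character/\code{AAString}) or an
#'   \code{\link{avehasProfile}} \code{DataFrame} (strands are then
#'   called on alignment columns, masking columns with residue occupancy
#'   below \code{minOccupancy}).
#' @param minLen,maxLen strand length bounds (residues).
#' @param threshold score threshold (fixed calibration constant by
#'   default).
#' @param window smoothing window.
#' @param minOccupancy mask profile columns below this occupancy.
#' @return a \code{\link{BetaTopology-class}} object.
#' @export
predictBetaTms <- function(x, minLen = 6L, maxLen = 14L,
                           threshold = .BETA_TMS_THRESHOLD,
                           window = .BETA_TMS_WINDOW, minOccupancy = 0.5) {
  if (is(x, "DataFrame") || is.data.frame(x)) {
    score <- x$amphipathicity + pmax(0, x$hydropathy)
    score[x$occupancy < minOccupancy] <- -Inf
    strands <- .callStrands(score, minLen, maxLen, threshold)
    return(BetaTopology(strands, caller = "avehas-consensus"))
  }
  s <- normalizeSeq(asSeqChar(x))
  if (nchar(s) < minLen)
    stop("sequence shorter than minLen", call. = FALSE)
  scale <- hydropathyScale("KD")
  h <- unname(scale[strsplit(s, "")[[1L]]])
  strands <- .callStrands(.strandScores(h, window), minLen, maxLen,
                          threshold)
  BetaTopology(strands, caller = "amphipathicity-window")
}

#' Per-family strand-count histograms
#'
#' Calls strands for every member of every family and tabulates the
#' counts, reporting the per-family modal strand number (the
#' family-consensus call, considerably more reliable than any
#' single-protein prediction) together with the full histogram.
#'
#' @param families named list of \code{AAStringSet}s (unaligned; gaps
#'   are stripped).
#' @param ... passed to \code{\link{predictBetaTms}}.
#' @return list with \code{summary} (data.frame: family, modal strand
#'   count, n members) and \code{histograms} (named list of tables).
#' @export
countTmsByFamily <- function(families, ...) {
  stopifnot(is.list(families), !is.null(names(families)))
  hists <- lapply(families, function(fam) {
    counts <- vapply(as.character(fam), function(s)
      nStrands(predictBetaTms(gsub("[-.]", "", s), ...)), integer(1))
    table(factor(counts, levels = sort(unique(counts))))
  })
  modal <- vapply(hists, function(h)
    as.integer(names(h)[which.max(h)]), integer(1))
  list(summary = data.frame(family = names(families),
                            modal_strands = modal,
                            n_members = vapply(families, length, integer(1)),
                            row.names = NULL),
       histograms = hists)
}

#' Tally families by strand count
#'
#' Aggregates modal per-family strand counts into a strand-number tally
#' (how many families have 8, 10, 12, ... strands), the format used to
#' contrast superfamily against non-superfamily topology spectra.
#'
#' @param counts output of \code{\link{countTmsByFamily}} (or an integer
#'   vector of per-family modal counts).
#' @return table of family counts per strand number.
#' @export
tallyStrandCounts <- function(counts) {
  v <- if (is.list(counts)) counts$summary$modal_strands else counts
  table(factor(v, levels = sort(unique(v))))
}

#' Write a profile TSV
#'
#' @param profile output of \code{\link{avehasProfile}}.
#' @param path TSV path.
#' @export
writeProfileTsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write strand intervals as BED-like TSV
#'
#' Coordinates are 1-based inclusive.
#'
#' @param topologies named list of \code{\link{BetaTopology-class}}.
#' @param path TSV path.
#' @export
writeStrandTsv <- function(topologies, path) {
  rows <- lapply(names(topologies), function(id) {
    tp <- topologies[[id]]
    if (nStrands(tp) == 0L) return(NULL)
    data.frame(id = id, start = IRanges::start(strandRanges(tp)),
               end = IRanges::end(strandRanges(tp)),
               strand_index = seq_len(nStrands(tp)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
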