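# Cross-family homology inference: local-search screens, emulated
# iterative expansion, transitive chains, and superfamily assignment.

bitScore <- function(score, ka) (ka$lambda * score - log(ka$K)) / log(2)

evalueOf <- function(score, m, n, ka) ka$K * m * n * exp(-ka$lambda * score)

#' Expand a family by iterative local search
#'
#' Emulates iterative database searching (PSI-BLAST style, two iterations
#' by default) over a local FASTA database: iteration 1 gathers database
#' members whose local-alignment E-value against the seed passes the first
#' cutoff; each subsequent iteration re-searches with every gathered
#' member as query using the next cutoff. E-values are Karlin-Altschul,
#' computed from the gapped local score with tabulated BLOSUM62
#' parameters and search space |query| x sum(|db|).
#'
#' @param seed a sequence (named character of length 1, or an id present
#'   in \code{database}).
#' @param database an \code{AAStringSet}.
#' @param iterations number of search iterations.
#' @param cutoffs per-iteration E-value thresholds (defaults 1e-4, 1e-6).
#' @param params an \code{\link{alnParams}} object.
#' @return the gathered subset of \code{database} (seed included).
#' @export
expandFamily <- function(seed, database, iterations = 2L,
                         cutoffs = c(1e-4, 1e-6), params = alnParams()) {
  stopifnot(length(database) > 0L, length(cutoffs) == iterations)
  ka <- kaParams(params@matrixName, gapped = TRUE)
  dbSeq <- asNamedChar(database)
  if (is.character(seed) && length(seed) == 1L && seed %in% names(dbSeq)) {
    seedId <- seed
  } else {
    seedId <- names(seed) %||% "query"
    if (!seedId %in% names(dbSeq)) {
      dbSeq <- c(setNames(asSeqChar(seed), seedId), dbSeq)
    }
  }
  enc <- lapply(dbSeq, function(s) aaEncode(normalizeSeq(s)))
  lens <- nchar(dbSeq)
  nTotal <- sum(lens)
  gathered <- seedId
  frontier <- seedId
  for (it in seq_len(iterations)) {
    if (!length(frontier)) break
    sc <- c_cross_scores(enc[frontier], enc, params@matrix, params@gapOpen,
                         params@gapExtend, TRUE, FALSE)
    hits <- character(0)
    for (qi in seq_along(frontier)) {
      ev <- evalueOf(sc[qi, ], lens[frontier[qi]], nTotal, ka)
      hits <- c(hits, names(dbSeq)[ev <= cutoffs[it]])
    }
    hits <- unique(hits)
    frontier <- setdiff(hits, gathered)
    gathered <- union(gathered, frontier)
  }
  keep <- names(database)[names(database) %in% gathered]
  out <- database[keep]
  if (!seedId %in% keep && seedId %in% names(dbSeq)) {
    out <- c(makeSeqSet(dbSeq[seedId]), out)
  }
  out
}

#' Targeted all-vs-all candidate screen
#'
#' Ranks all cross pairs of two sequence sets by raw local-alignment
#' score, the rapid first pass used to surface distant-homolog candidates
#' that are then confirmed with \code{\link{segmentShuffleZ}}.
#'
#' @param setA,setB \code{AAStringSet}s (or named character vectors).
#' @param params an \code{\link{alnParams}} object.
#' @param topK number of top-ranked pairs to return (Inf for all).
#' @return data.frame (idA, idB, score, bits, evalue) sorted by
#'   decreasing score; ties broken by id order for determinism.
#' @export
screenPairs <- function(setA, setB, params = alnParams(), topK = 25L) {
  a <- asNamedChar(setA); b <- asNamedChar(setB)
  stopifnot(length(a) > 0L, length(b) > 0L)
  ka <- kaParams(params@matrixName, gapped = TRUE)
  encA <- lapply(a, function(s) aaEncode(normalizeSeq(s)))
  encB <- lapply(b, function(s) aaEncode(normalizeSeq(s)))
  sc <- c_cross_scores(encA, encB, params@matrix, params@gapOpen,
                       params@gapExtend, TRUE, FALSE)
  df <- data.frame(idA = rep(names(a), times = length(b)),
                   idB = rep(names(b), each = length(a)),
                   score = as.vector(sc), stringsAsFactors = FALSE)
  df$bits <- bitScore(df$score, ka)
  df$evalue <- evalueOf(df$score, nchar(a)[match(df$idA, names(a))],
                        sum(nchar(b)), ka)
  df <- df[order(-df$score, df$idA, df$idB), , drop = FALSE]
  rownames(df) <- NULL
  head(df, n = if (is.finite(topK)) topK else nrow(df))
}

.seqWithId <- function(x, default) {
  s <- asSeqChar(x)
  id <- if (!is.null(names(x)) && nzchar(names(x)[1L])) names(x)[1L] else default
  setNames(s, id)
}

#' Verify a transitive homology chain
#'
#' Implements the superfamily principle for an A-B-C-D chain: the direct
#' A-vs-D comparison is computed first and, if it meets the SD threshold
#' on a comparable segment (at least \code{rule@minLength} residues), the
#' chain is accepted outright without bridges. Otherwise the three links
#' A-B, B-C and C-D are each scored with \code{\link{segmentShuffleZ}} and
#' the chain is accepted only if every link strictly exceeds the
#' threshold. B and C may coincide (or equal A and D for a direct 2-node
#' chain).
#'
#' @param a,b,c,d sequences (named character vectors or single-element
#'   \code{AAStringSet}s; names become chain ids).
#' @param params an \code{\link{alnParams}} object.
#' @param rule a \code{\link{segmentRule}}.
#' @param nShuffles shuffles per comparison.
#' @param seed master seed (per-link seeds are derived from it).
#' @param direct optional precomputed result of
#'   \code{\link{segmentShuffleZ}(a, d)}: the direct comparison is a
#'   single statistical test, so callers that have already performed it
#'   (e.g. the family screen) pass it here instead of re-running it.
#' @return a \code{\link{HomologyChain-class}} object.
#' @export
verifyChain <- function(a, b, c, d, params = alnParams(),
                        rule = segmentRule(), nShuffles = 2000L, seed = 1L,
                        direct = NULL) {
  a <- .seqWithId(a, "A"); b <- .seqWithId(b, "B")
  c <- .seqWithId(c, "C"); d <- .seqWithId(d, "D")
  ids <- c(names(a), names(b), names(c), names(d))
  tooShort <- nchar(c(a, b, c, d)) < rule@minLength
  if (any(tooShort)) {
    return(new("HomologyChain", ids = ids, linkZ = numeric(0),
               linkSegLen = integer(0), directZ = NA_real_,
               directSegLen = NA_integer_, accepted = FALSE,
               method = "none",
               reason = sprintf("below %d aa", rule@minLength)))
  }
  # direct comparison: threshold met "equal to or exceeded" accepts alone
  if (is.null(direct))
    direct <- segmentShuffleZ(a, d, params, rule, nShuffles,
                              seed = deriveSeed(seed, 0L), strict = FALSE)
  dz <- if (is.null(direct$z)) NA_real_ else zSD(direct$z)
  if (isTRUE(direct$pass)) {
    return(new("HomologyChain", ids = ids, linkZ = numeric(0),
               linkSegLen = integer(0), directZ = dz,
               directSegLen = direct$segLen, accepted = TRUE,
               method = "direct", reason = ""))
  }
  links <- list(list(a, b), list(b, c), list(c, d))
  linkZ <- rep(NA_real_, 3)
  segLen <- integer(3)
  ok <- logical(3)
  for (k in 1:3) {
    # identical link members (e.g. b == c) pass trivially
    if (identical(asSeqChar(links[[k]][[1]]), asSeqChar(links[[k]][[2]])) &&
        nchar(asSeqChar(links[[k]][[1]])) >= rule@minLength) {
      linkZ[k] <- Inf
      segLen[k] <- nchar(asSeqChar(links[[k]][[1]]))
      ok[k] <- TRUE
      next
    }
    r <- segmentShuffleZ(links[[k]][[1]], links[[k]][[2]], params, rule,
                         nShuffles, seed = deriveSeed(seed, k),
                         strict = TRUE)
    linkZ[k] <- if (is.null(r$z)) NA_real_ else zSD(r$z)
    segLen[k] <- r$segLen
    ok[k] <- isTRUE(r$pass)
    if (!ok[k]) break   # one failed link sinks the chain
  }
  accepted <- all(ok)
  new("HomologyChain", ids = ids, linkZ = linkZ, linkSegLen = segLen,
      directZ = dz, directSegLen = direct$segLen %||% NA_integer_,
      accepted = accepted, method = if (accepted) "chained" else "none",
      reason = if (accepted) "" else "link below threshold")
}

#' Assign families to superfamilies by transitive closure
#'
#' Builds the family-level evidence graph (node = family, edge = at least
#' one accepted chain or direct comparison between members of the two
#' families) and returns its connected components, labelled SF1, SF2, ...
#' in decreasing size order. Families without any accepted evidence are
#' reported with status "no evidence" — failure to establish homology is
#' never taken as evidence of non-membership.
#'
#' @param evidence data.frame with columns \code{familyA}, \code{familyB}
#'   (or \code{idA}/\code{idB} plus \code{familyOf} to map ids), optional
#'   \code{z} and \code{method}, one row per accepted piece of evidence.
#' @param familyOf either a character vector of all family names under
#'   study, or a named character vector mapping sequence ids to families
#'   (its unique values define the family universe).
#' @return a \code{\link{SuperfamilyAssignment-class}} object.
#' @export
buildSuperfamilies <- function(evidence, familyOf) {
  if (!is.null(names(familyOf))) {
    families <- unique(unname(familyOf))
    idmap <- familyOf
  } else {
    families <- unique(familyOf)
    idmap <- NULL
  }
  ev <- evidence
  if (!is.null(ev) && nrow(ev) > 0L) {
    if (!"familyA" %in% names(ev)) {
      if (is.null(idmap))
        stop("evidence has no familyA/familyB and familyOf is unnamed",
             call. = FALSE)
      ev$familyA <- unname(idmap[ev$idA])
      ev$familyB <- unname(idmap[ev$idB])
    }
    bad <- !(ev$familyA %in% families) | !(ev$familyB %in% families)
    if (any(bad))
      stop("evidence references unknown families: ",
           paste(unique(c(ev$familyA[bad], ev$familyB[bad])), collapse = ", "),
           call. = FALSE)
  } else {
    ev <- data.frame(familyA = character(0), familyB = character(0))
  }
  g <- igraph::graph_from_data_frame(
    ev[, c("familyA", "familyB"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = families))
  comp <- igraph::components(g)
  # deterministic labels: decreasing size, ties by lexicographically first
  # family name in the component
  grp <- split(families, comp$membership[families])
  firsts <- vapply(grp, function(f) min(f), character(1))
  ordc <- order(-vapply(grp, length, integer(1)), firsts)
  labels <- setNames(paste0("SF", seq_along(grp)), names(grp)[ordc])
  famComp <- setNames(labels[as.character(comp$membership[families])],
                      families)
  members <- split(families, famComp)
  members <- members[order(names(members))]
  hasEvidence <- families %in% c(ev$familyA, ev$familyB)
  status <- setNames(ifelse(hasEvidence, "assigned", "no evidence"),
                     families)
  if (!"z" %in% names(ev)) ev$z <- rep(NA_real_, nrow(ev))
  if (!"method" %in% names(ev)) ev$method <- rep(NA_character_, nrow(ev))
  new("SuperfamilyAssignment", familyComponent = famComp, members = members,
      evidence = ev, status = status)
}

#' Screen families for homology evidence
#'
#' Runs the full cross-family protocol on a collection of families: for
#' every family pair the top-ranked candidate pair from the rapid local
#' screen is confirmed with a comparable-segment shuffle score; when the
#' direct comparison fails, bridge candidates are sought automatically by
#' expanding both query sets over the pooled database and verifying
#' A-B-C-D chains through the top-k bridging pairs.
#'
#' @param families named list of \code{AAStringSet}s (one per family).
#' @param params an \code{\link{alnParams}} object.
#' @param rule a \code{\link{segmentRule}}.
#' @param nShuffles shuffles per confirmed comparison.
#' @param topK bridge candidates tried per family pair.
#' @param seed master seed.
#' @param tryChains attempt transitive chains when the direct comparison
#'   fails (default TRUE).
#' @param bridgeEvalueMax E-value prefilter for bridge candidates (default
#'   1e-6, the stringent second-iteration search cutoff): pairs
#'   scoring worse are not shuffle-confirmed.
#' @return list with \code{edges} (data.frame of accepted evidence:
#'   familyA, familyB, z, method), \code{chains} (accepted
#'   \code{HomologyChain}s), \code{tested} (all pairwise attempts).
#' @export
screenFamilies <- function(families, params = alnParams(),
                           rule = segmentRule(), nShuffles = 1000L,
                           topK = 5L, seed = 1L, tryChains = TRUE,
                           bridgeEvalueMax = 1e-6) {
  stopifnot(is.list(families), length(families) >= 2L,
            !is.null(names(families)))
  famNames <- names(families)
  pool <- do.call(c, lapply(unname(families), asNamedChar))
  poolSet <- makeSeqSet(pool, sourceTag = "screen-pool")
  famOf <- setNames(rep(famNames, vapply(families, length, integer(1))),
                    names(pool))
  edges <- list()
  chains <- list()
  tested <- list()
  pairIdx <- 0L
  # bridge-pair shuffle results are cached across family pairs (the same
  # candidate pair is often surfaced by several expansions); the cached
  # seed is a deterministic function of the pair ids, so results do not
  # depend on enumeration order
  bridgeCache <- new.env(parent = emptyenv())
  bridgeTest <- function(x, y) {
    key <- paste(sort(c(names(x), names(y))), collapse = "\r")
    hit <- bridgeCache[[key]]
    if (!is.null(hit)) return(hit)
    res <- segmentShuffleZ(x, y, params, rule, nShuffles,
                           seed = deriveSeed(seed,
                                             sum(utf8ToInt(key)) %% 99991L),
                           strict = TRUE)
    bridgeCache[[key]] <- res
    res
  }
  for (i in seq_len(length(families) - 1L)) {
    for (j in (i + 1L):length(families)) {
      pairIdx <- pairIdx + 1L
      fa <- famNames[i]; fb <- famNames[j]
      top <- screenPairs(families[[i]], families[[j]], params, topK = 1L)
      aStar <- setNames(as.character(families[[i]][top$idA[1]]), top$idA[1])
      bStar <- setNames(as.character(families[[j]][top$idB[1]]), top$idB[1])
      direct <- segmentShuffleZ(aStar, bStar, params, rule, nShuffles,
                                seed = deriveSeed(seed, pairIdx * 37L),
                                strict = FALSE)
      dz <- if (is.null(direct$z)) NA_real_ else zSD(direct$z)
      tested[[length(tested) + 1L]] <-
        data.frame(familyA = fa, familyB = fb, idA = top$idA[1],
                   idB = top$idB[1], z = dz, method = "direct",
                   accepted = isTRUE(direct$pass))
      if (isTRUE(direct$pass)) {
        edges[[length(edges) + 1L]] <-
          data.frame(familyA = fa, familyB = fb, z = dz, method = "direct")
        next
      }
      if (!tryChains) next
      expA <- expandFamily(top$idA[1], poolSet, params = params)
      expB <- expandFamily(top$idB[1], poolSet, params = params)
      cand <- screenPairs(expA, expB, params, topK = Inf)
      cand <- cand[cand$idA != cand$idB &
                     cand$evalue <= bridgeEvalueMax, , drop = FALSE]
      # skip bridges that just reproduce the failed direct pair
      cand <- cand[!(cand$idA == top$idA[1] & cand$idB == top$idB[1]), ,
                   drop = FALSE]
      cand <- head(cand, topK)
      for (k in seq_len(nrow(cand))) {
        x <- setNames(as.character(poolSet[cand$idA[k]]), cand$idA[k])
        y <- setNames(as.character(poolSet[cand$idB[k]]), cand$idB[k])
        # the bridge (middle) link is usually the weakest: test it first
        # and skip the candidate cheaply when it fails
        if (!identical(asSeqChar(x), asSeqChar(y)) &&
            !isTRUE(bridgeTest(x, y)$pass)) next
        ch <- verifyChain(aStar, x, y, bStar, params, rule, nShuffles,
                          seed = deriveSeed(seed, pairIdx * 37L + k),
                          direct = direct)
        if (isAccepted(ch)) {
          z3 <- min(zSD(ch))
          edges[[length(edges) + 1L]] <-
            data.frame(familyA = fa, familyB = fb, z = z3,
                       method = "chained")
          chains[[length(chains) + 1L]] <- ch
          break
        }
      }
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(familyA = character(0), familyB = character(0),
                    z = numeric(0), method = character(0)),
       chains = chains,
       tested = do.call(rbind, tested),
       familyOf = famOf)
}

#' Write a chain report
#'
#' TSV with one row per verified chain: the four protein ids, the three
#' link comparison scores and the direct A-vs-D score (SD units).
#'
#' @param chains list of \code{\link{HomologyChain-class}} objects.
#' @param path output TSV path.
#' @export
writeChainReport <- function(chains, path) {
  rows <- lapply(chains, function(ch) {
    lz <- zSD(ch)
    data.frame(proteinA = ch@ids[1], proteinB = ch@ids[2],
               proteinC = ch@ids[3], proteinD = ch@ids[4],
               z_AB = if (length(lz)) round(lz[1], 1) else NA_real_,
               z_BC = if (length(lz) > 1) round(lz[2], 1) else NA_real_,
               z_CD = if (length(lz) > 2) round(lz[3], 1) else NA_real_,
               z_AD = round(ch@directZ, 1),
               accepted = ch@accepted, method = ch@method)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
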