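#' Read a set of protein sequences from FASTA
#'
#' Reads unaligned or aligned FASTA into an
#' \link[Biostrings]{AAStringSet}. Sequences are upper-cased, ambiguity
#' codes (B/Z/J/U/O) are mapped to X, and gap characters (\code{-},
#' \code{.}) are stripped unless \code{aligned = TRUE}. TC-style
#' identifiers of the form \code{1.B.<family>.<subfamily>.<protein>} are
#' parsed into a \code{family} column of \code{mcols}.
#'
#' @param path path to a FASTA file.
#' @param aligned keep gap characters (aligned FASTA dialect)?
#' @param sourceTag free-text provenance tag stored in
#'   \code{metadata(x)$source}.
#' @return an \code{AAStringSet} with unique names; \code{mcols} holds
#'   \code{description} and \code{family}.
#' @export
readFastaSet <- function(path, aligned = FALSE, sourceTag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1L])
    stop("malformed FASTA: first non-empty line (line 1) is not a header",
         call. = FALSE)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S*\\s*", "", headers))
  if (any(!nzchar(ids))) {
    bad <- which(hdr)[!nzchar(ids)][1L]
    stop("malformed FASTA header at line ", bad, call. = FALSE)
  }
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  full <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  full[names(seqs)] <- seqs
  if (any(!nzchar(full))) {
    i <- which(!nzchar(full))[1L]
    stop("FASTA entry '", ids[i], "' has an empty sequence", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  full <- vapply(full, normalizeSeq, character(1), stripGaps = !aligned)
  makeSeqSet(full, ids = ids, description = desc, sourceTag = sourceTag)
}

#' Build a sequence set from character vectors
#'
#' @param seqs character vector of sequences (optionally named).
#' @param ids identifiers (default: names of \code{seqs}).
#' @param description per-sequence free text.
#' @param sourceTag provenance tag.
#' @return an \code{AAStringSet}.
#' @export
makeSeqSet <- function(seqs, ids = names(seqs),
                       description = character(length(seqs)),
                       sourceTag = "in-memory") {
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids))
    stop("ids must be unique within a set", call. = FALSE)
  seqs <- vapply(unname(seqs), normalizeSeq, character(1), stripGaps = FALSE)
  x <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    description = as.character(description),
    family = tcFamily(ids))
  S4Vectors::metadata(x)$source <- sourceTag
  x
}

#' Write a sequence set to FASTA
#'
#' @param x an \code{AAStringSet} (or named character vector).
#' @param path output path.
#' @param width line-wrap width.
#' @export
writeFastaSet <- function(x, path, width = 70L) {
  seqs <- asNamedChar(x)
  ids <- names(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse TC-style identifiers
#'
#' Decomposes Transporter Classification identifiers of the form
#' \code{1.B.<family>.<subfamily>.<protein>} into numeric components.
#' Non-TC identifiers yield NA rows (total function, never errors).
#'
#' @param ids character vector of identifiers.
#' @return data.frame with columns \code{id}, \code{family},
#'   \code{subfamily}, \code{protein} (integer, NA for non-TC ids).
#' @examples
#' parseTcId(c("1.B.4.2.4", "Req1"))
#' @export
parseTcId <- function(ids) {
  pat <- "^1\\.B\\.([0-9]+)\\.([0-9]+)\\.([0-9]+)$"
  m <- regmatches(ids, regexec(pat, ids, ignore.case = TRUE))
  comp <- t(vapply(m, function(g)
    if (length(g) == 4L) as.integer(g[2:4]) else rep(NA_integer_, 3L),
    integer(3)))
  data.frame(id = ids, family = comp[, 1L], subfamily = comp[, 2L],
             protein = comp[, 3L], stringsAsFactors = FALSE)
}

#' Family label from an identifier
#'
#' For TC-style ids the label is the first three dotted components
#' (e.g. \code{"1.B.4"}); other ids give NA.
#'
#' @param ids character vector.
#' @return character vector of family labels (NA where not TC-style).
#' @export
tcFamily <- function(ids) {
  p <- parseTcId(ids)
  ifelse(is.na(p$family), NA_character_, paste0("1.B.", p$family))
}

#' Pairwise percent identity
#'
#' Identity from the optimal global alignment of two sequences, with a
#' configurable denominator. The redundancy filter uses the CD-HIT
#' convention: identities divided by the length of the shorter unaligned
#' sequence.
#'
#' @param a,b sequences (character strings).
#' @param params an \code{\link{alnParams}} object.
#' @param denominator \code{"shorter"} (default), \code{"alignment"}
#'   (alignment columns) or \code{"longer"}.
#' @return identity as a fraction in [0, 1].
#' @export
pairIdentity <- function(a, b, params = alnParams(),
                         denominator = c("shorter", "alignment", "longer")) {
  denominator <- match.arg(denominator)
  a <- normalizeSeq(asSeqChar(a)); b <- normalizeSeq(asSeqChar(b))
  tb <- c_align_traceback(aaEncode(a), aaEncode(b), params@matrix,
                          params@gapOpen, params@gapExtend, FALSE,
                          params@endGapsFree)
  ca <- strsplit(a, "")[[1L]][tb$ia]
  cb <- strsplit(b, "")[[1L]][tb$ib]
  nid <- sum(!is.na(tb$ia) & !is.na(tb$ib) & ca == cb, na.rm = TRUE)
  den <- switch(denominator,
                shorter = min(nchar(a), nchar(b)),
                longer = max(nchar(a), nchar(b)),
                alignment = length(tb$ia))
  nid / den
}

#' Reduce redundancy at an identity cutoff
#'
#' Greedy longest-first clustering: sequences are visited in order of
#' decreasing length (ties broken lexicographically by id); each sequence
#' joins the first existing representative with which its pairwise
#' identity (global alignment, identities over the shorter sequence)
#' exceeds the cutoff, otherwise it founds a new cluster. The retained set
#' contains one representative per cluster, so no two retained sequences
#' are more than \code{cutoff} identical. The default cutoff (0.85) is
#' used for homology work; 0.70 gives the sparser sets used for profile
#' plots and trees.
#'
#' @param x an \code{AAStringSet} (or named character vector).
#' @param cutoff identity cutoff in (0, 1].
#' @param params alignment parameters for the identity computation.
#' @return an \code{AAStringSet} of representatives;
#'   \code{metadata(.)$clusters} is a data.frame
#'   (representative_id, member_id, identity).
#' @export
reduceRedundancy <- function(x, cutoff = 0.85, params = alnParams()) {
  stopifnot(cutoff > 0, cutoff <= 1)
  seqs <- asNamedChar(x)
  if (length(seqs) == 0L) return(makeSeqSet(character(0), character(0)))
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  repIds <- character(0)
  memb <- list()
  for (k in ord) {
    placed <- FALSE
    for (r in repIds) {
      idy <- pairIdentity(seqs[[r]], seqs[[k]], params)
      if (idy > cutoff) {
        memb[[r]] <- rbind(memb[[r]],
                           data.frame(representative_id = r,
                                      member_id = ids[k],
                                      identity = idy))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      r <- ids[k]
      repIds <- c(repIds, r)
      memb[[r]] <- data.frame(representative_id = r, member_id = r,
                              identity = 1)
    }
  }
  keep <- ids[ids %in% repIds]   # preserve input order among representatives
  out <- makeSeqSet(seqs[keep], ids = keep,
                    sourceTag = sprintf("reduceRedundancy(cutoff=%g)", cutoff))
  S4Vectors::metadata(out)$clusters <-
    do.call(rbind, c(unname(memb), list(make.row.names = FALSE)))
  out
}

#' Write a cluster-membership report
#'
#' @param x output of \code{\link{reduceRedundancy}}.
#' @param path TSV output path.
#' @export
writeClusterReport <- function(x, path) {
  cl <- S4Vectors::metadata(x)$clusters
  if (is.null(cl)) stop("no cluster metadata on this set", call. = FALSE)
  write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Coerce AAString / AAStringSet element / character to a plain string.
asSeqChar <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    return(x)
  }
  as.character(x)[1L]
}

# Coerce a set (AAStringSet or character vector) to a *named* character
# vector; base as.character() would drop names from a character input.
asNamedChar <- function(x) {
  nms <- names(x)
  out <- as.character(x)
  names(out) <- nms
  out
}
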