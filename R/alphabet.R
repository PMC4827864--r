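# Internal amino-acid alphabet: the 20 canonical residues plus X.
# Ambiguity codes B/Z/J and the rare U/O are collapsed to X on input;
# X scores 0 against everything.

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.pkg_env <- new.env(parent = emptyenv())

.aa_lut <- local({
  lut <- rep(NA_integer_, 127)
  for (i in seq_along(.AA_LETTERS)) lut[utf8ToInt(.AA_LETTERS[i])] <- i
  for (amb in c("B", "Z", "J", "U", "O")) lut[utf8ToInt(amb)] <- 21L
  lut
})

# Encode one sequence string to 0-based integer codes.
aaEncode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(toupper(x))
  if (any(codes > 127L))
    stop("non-ASCII character in sequence", call. = FALSE)
  idx <- .aa_lut[codes]
  if (anyNA(idx)) {
    bad <- unique(intToUtf8(codes[is.na(idx)], multiple = TRUE))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx - 1L
}

aaDecode <- function(codes) {
  paste(.AA_LETTERS[codes + 1L], collapse = "")
}

# Normalize a raw sequence string: upper-case, strip gaps if requested,
# map ambiguity codes to X.
normalizeSeq <- function(x, stripGaps = TRUE) {
  x <- toupper(x)
  if (stripGaps) x <- gsub("[-.]", "", x)
  x <- chartr("BZJUO", "XXXXX", x)
  x
}

#' Substitution matrix in the package alphabet
#'
#' Returns a 21 x 21 integer substitution matrix (20 canonical residues
#' plus X) in the package's internal residue order. Named matrices are
#' taken from \pkg{Biostrings}; the X row/column is zeroed so that
#' ambiguous residues are scoring-neutral.
#'
#' @param name matrix name, e.g. \code{"BLOSUM62"} (default),
#'   \code{"BLOSUM50"}, \code{"PAM250"}.
#' @return integer matrix with dimnames in the package alphabet.
#' @export
getSubMatrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(e[[name]]))
    stop("unknown substitution matrix: ", name, call. = FALSE)
  full <- e[[name]]
  canon <- .AA_LETTERS[1:20]
  m <- matrix(0L, 21L, 21L, dimnames = list(.AA_LETTERS, .AA_LETTERS))
  m[canon, canon] <- as.integer(full[canon, canon])
  # X is scoring-neutral by package convention
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  .pkg_env[[key]] <- m
  m
}

# Karlin-Altschul parameters used to express local scores in bits and to
# emulate E-values. Values are the standard BLAST estimates for BLOSUM62;
# the gapped entry (for the default gapped local search) is the BLAST
# default-gap estimate, used as an approximation for nearby gap settings.
.KA_TABLE <- data.frame(
  matrix_name = c("BLOSUM62", "BLOSUM62"),
  gapped = c(FALSE, TRUE),
  lambda = c(0.3176, 0.267),
  K = c(0.134, 0.041),
  stringsAsFactors = FALSE
)

kaParams <- function(matrixName = "BLOSUM62", gapped = TRUE) {
  hit <- .KA_TABLE[.KA_TABLE$matrix_name == matrixName &
                     .KA_TABLE$gapped == gapped, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("no Karlin-Altschul parameters tabulated for matrix '", matrixName,
         "'; use BLOSUM62 or supply scores directly", call. = FALSE)
  list(lambda = hit$lambda[1L], K = hit$K[1L])
}
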