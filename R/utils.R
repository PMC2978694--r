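# Shared low-level helpers: base coding, reverse complement, coordinates.
# All coordinates in site tables are 0-based half-open on the sense strand.

DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the package; accepts
#' a character vector and preserves its length. Non-ACGT letters other than
#' N are rejected.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("TGTGACGTCACA")
#' @export
revComp <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad))
    stop("non-DNA letters in sequence(s): ", paste(which(bad), collapse = ", "))
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Integer codes 1..4 for A,C,G,T; NA for anything else (N etc.).
.seqCodes <- function(s) {
  m <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
  m
}

.codesToSeq <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

# Reverse complement of a 4 x w count/probability matrix: complement the
# base axis (A<->T, C<->G) and reverse the position axis.
.revCompMatrix <- function(m) {
  m[4:1, ncol(m):1, drop = FALSE]
}

# 0-based half-open slice of a sequence string.
.slice <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

.checkSeed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required")
  as.integer(seed)
}

# Deterministic sub-seed derivation that stays inside 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

# Sum of per-window log-odds scores for every window of width w.
# lo: 4 x w matrix; codes: integer codes of the sequence (NA allowed).
# Windows containing NA (ambiguous base) score -Inf.
.windowScores <- function(lo, codes, w = ncol(lo)) {
  nWin <- length(codes) - w + 1L
  if (nWin < 1L) return(numeric(0))
  s <- numeric(nWin)
  for (k in seq_len(w)) {
    ck <- codes[k:(k + nWin - 1L)]
    v <- lo[cbind(ck, k)]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

# Normalize heterogeneous sequence input (character vector, DNAStringSet,
# list) to a named character vector of uppercase sequences.
.asSeqVector <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.list(x)) {
    out <- vapply(x, as.character, character(1))
  } else if (is.character(x)) {
    out <- x
  } else {
    stop(what, " must be a character vector or an XStringSet")
  }
  out <- toupper(out)
  if (is.null(names(out)) || anyDuplicated(names(out)))
    names(out) <- if (is.null(names(out)))
      sprintf("seq%04d", seq_along(out)) else make.unique(names(out))
  out
}
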