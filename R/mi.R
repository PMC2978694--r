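# Mutual information (covariance dependency) between paired amino-acid
# and nucleotide alignment columns.

#' Mutual information between two paired alignment columns
#'
#' Plug-in estimate in bits, \eqn{\sum f(a,n) \log_2 [f(a,n)/(f(a) f(n))]}
#' over observed symbol pairs. Row i of both columns must come from the
#' same regulator/site pair. Pairs containing a gap in either column are
#' dropped before estimation; a constant column gives exactly 0 bits.
#'
#' @param aa character vector of amino-acid symbols.
#' @param nt character vector of nucleotide symbols, same length.
#' @param gapChars symbols treated as gaps (pairwise deletion).
#' @param correction \code{"none"} (plug-in, the default) or
#'   \code{"miller-madow"} for the first-order small-sample bias
#'   correction.
#' @return mutual information in bits (non-negative for the plug-in
#'   estimator; the corrected variant can dip below zero and is floored
#'   at 0).
#' @examples
#' columnMI(c("K", "K", "Y", "Y"), c("T", "T", "G", "G"))  # 1 bit
#' @export
columnMI <- function(aa, nt, gapChars = c("-", "."),
                     correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  stopifnot(length(aa) == length(nt))
  if (length(aa) < 2L) stop("need at least 2 paired rows")
  ok <- !(aa %in% gapChars) & !(nt %in% gapChars) & !is.na(aa) & !is.na(nt)
  aa <- aa[ok]; nt <- nt[ok]
  n <- length(aa)
  if (n == 0L) stop("zero usable (gap-free) pairs")
  joint <- table(aa, nt) / n
  fa <- rowSums(joint); fn <- colSums(joint)
  idx <- joint > 0
  mi <- sum(joint[idx] * log2(joint[idx] /
                                (outer(fa, fn)[idx])))
  if (correction == "miller-madow") {
    r <- sum(fa > 0); c <- sum(fn > 0)
    mi <- mi - (r - 1) * (c - 1) / (2 * n * log(2))
  }
  max(mi, 0)
}

#' Mutual-information matrix between a domain and a site alignment
#'
#' Computes \code{\link{columnMI}} for every (amino-acid column,
#' nucleotide column) pair after pairing rows through regulator ids:
#' every site row must map to exactly one domain row.
#'
#' @param alignment a \code{\linkS4class{DomainAlignment}}.
#' @param sites character vector of equal-length site sequences.
#' @param pairing character vector, one regulator id per site row; every
#'   id must name a sequence of \code{alignment}.
#' @param ... passed to \code{\link{columnMI}}.
#' @return numeric matrix (AA columns x NT columns) of mutual information
#'   in bits, with dimnames \code{AA<i>} / \code{NT<j>} (NT columns indexed
#'   by site position, left to right) and attribute \code{"n_pairs"}.
#' @export
miMatrix <- function(alignment, sites, pairing, ...) {
  stopifnot(methods::is(alignment, "DomainAlignment"))
  sites <- .asSeqVector(sites, "sites")
  if (length(sites) < 2L) stop("need at least 2 site rows")
  stopifnot(length(pairing) == length(sites))
  dom <- alignedSeqs(alignment)
  missing <- setdiff(unique(pairing), names(dom))
  if (length(missing))
    stop("site rows map to unknown regulators: ",
         paste(missing, collapse = ", "))
  if (length(unique(nchar(sites))) != 1L)
    stop("ragged site alignment")
  aaM <- do.call(rbind, strsplit(unname(dom[pairing]), "", fixed = TRUE))
  ntM <- do.call(rbind, strsplit(unname(sites), "", fixed = TRUE))
  out <- matrix(0, ncol(aaM), ncol(ntM),
                dimnames = list(paste0("AA", seq_len(ncol(aaM))),
                                paste0("NT", seq_len(ncol(ntM)))))
  for (i in seq_len(ncol(aaM)))
    for (j in seq_len(ncol(ntM)))
      out[i, j] <- columnMI(aaM[, i], ntM[, j], ...)
  attr(out, "n_pairs") <- nrow(aaM)
  out
}

#' Rank cells of a mutual-information matrix
#'
#' Orders all cells by decreasing mutual information; ties are broken by
#' (amino-acid index, nucleotide index) so the ranking is deterministic.
#'
#' @param mi matrix from \code{\link{miMatrix}}.
#' @param k number of top cells to return (default all).
#' @return data.frame with columns \code{aa_col}, \code{nt_col}, \code{mi},
#'   sorted by rank.
#' @export
topMICells <- function(mi, k = length(mi)) {
  idx <- which(!is.na(mi), arr.ind = TRUE)
  df <- data.frame(aa_col = idx[, 1], nt_col = idx[, 2],
                   mi = mi[idx])
  df <- df[order(-df$mi, df$aa_col, df$nt_col), , drop = FALSE]
  rownames(df) <- NULL
  head(df, k)
}

#' Permutation null for the maximum of an MI matrix
#'
#' Recomputes the matrix maximum after randomly permuting the pairing
#' between site rows and regulators, \code{nPerm} times. Used to check
#' that an observed maximum stands above what unpaired alignments
#' produce.
#'
#' @inheritParams miMatrix
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return numeric vector of \code{nPerm} permuted-matrix maxima.
#' @export
miPermutationNull <- function(alignment, sites, pairing, nPerm = 200,
                              seed = 1L) {
  set.seed(.checkSeed(seed))
  vapply(seq_len(nPerm), function(i) {
    max(miMatrix(alignment, sites, sample(pairing)))
  }, numeric(1))
}
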