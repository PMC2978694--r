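# Domain-set curation and recognition-class partitioning in the fixed
# alignment coordinate frame.

#' Build a domain record table
#'
#' Convenience constructor for the tabular domain-record carrier used by
#' the curation filters: one row per protein with its raw and aligned
#' domain sequence and the core-domain annotation (core-domain scanning is
#' an upstream annotation, not recomputed here).
#'
#' @param id character ids (unique).
#' @param aligned_seq aligned sequences (gaps as \code{-}), equal widths.
#' @param organism optional organism labels.
#' @param has_core_domain logical, whether the 26-residue core
#'   helix-turn-helix domain was detected upstream.
#' @return data.frame with columns \code{id}, \code{organism},
#'   \code{raw_seq}, \code{aligned_seq}, \code{has_core_domain}.
#' @export
domainRecords <- function(id, aligned_seq, organism = NA_character_,
                          has_core_domain = TRUE) {
  stopifnot(length(id) == length(aligned_seq), !anyDuplicated(id))
  aligned_seq <- toupper(aligned_seq)
  if (length(unique(nchar(aligned_seq))) > 1L)
    stop("ragged alignment: aligned_seq widths differ")
  data.frame(id = as.character(id),
             organism = rep_len(organism, length(id)),
             raw_seq = gsub("[-.]", "", aligned_seq),
             aligned_seq = aligned_seq,
             has_core_domain = rep_len(has_core_domain, length(id)),
             stringsAsFactors = FALSE)
}

#' Filter domain records by length and core-domain presence
#'
#' Keeps records whose ungapped length lies inside \code{lengthRange}
#' (inclusive at both ends) and, when \code{requireCore}, whose core-domain
#' flag is set. Multi-domain proteins are expected to be excluded by the
#' caller before this step.
#'
#' @param records data.frame from \code{\link{domainRecords}}.
#' @param lengthRange numeric \code{c(min, max)}.
#' @param requireCore drop records lacking the core domain.
#' @return the filtered records.
#' @export
filterDomains <- function(records, lengthRange = c(45, 75),
                          requireCore = TRUE) {
  stopifnot(lengthRange[1] <= lengthRange[2])
  len <- nchar(records$raw_seq)
  keep <- len >= lengthRange[1] & len <= lengthRange[2]
  if (requireCore) keep <- keep & records$has_core_domain
  records[keep, , drop = FALSE]
}

#' Collapse exact-duplicate domain sequences
#'
#' Overrepresented identical domain sequences (strain variants of the same
#' regulator) are collapsed to one representative: the first id in sorted
#' order. The number of removed records is reported in a message and
#' attached as attribute \code{"n_removed"}.
#'
#' @param records data.frame with columns \code{id}, \code{raw_seq}.
#' @return deduplicated records.
#' @export
dedupeDomains <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$id)
  sorted <- records[ord, , drop = FALSE]
  keep <- !duplicated(sorted$raw_seq)
  out <- sorted[keep, , drop = FALSE]
  nRemoved <- nrow(records) - nrow(out)
  if (nRemoved > 0L)
    message("dedupeDomains: removed ", nRemoved, " duplicate sequence(s)")
  attr(out, "n_removed") <- nRemoved
  out
}

#' Remove alignment columns dominated by gaps
#'
#' Drops every column whose gap fraction is strictly greater than
#' \code{maxGapFraction} (a column with exactly that fraction is kept).
#' The surviving columns define the fixed coordinate frame; the returned
#' map gives, for each kept column, its index in the input alignment.
#'
#' @param alignment a \code{\linkS4class{DomainAlignment}} or named
#'   character vector of equal-width aligned sequences.
#' @param maxGapFraction threshold on the per-column gap fraction.
#' @return list with \code{alignment} (a \code{DomainAlignment} in the new
#'   frame) and \code{keptColumns} (integer map new index -> old index).
#' @export
dropGappyColumns <- function(alignment, maxGapFraction = 0.80) {
  seqs <- if (methods::is(alignment, "DomainAlignment"))
    alignedSeqs(alignment) else .asSeqVector(alignment, "alignment")
  if (length(unique(nchar(seqs))) > 1L)
    stop("ragged alignment")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  gapFrac <- colMeans(m == "-" | m == ".")
  kept <- which(gapFrac <= maxGapFraction)
  out <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(seqs)
  list(alignment = DomainAlignment(out), keptColumns = kept)
}

#' Recognition and structural residues of aligned domains
#'
#' Extracts the residues at the fixed-frame specificity and structural
#' columns (by default column 5, the recognition helix 15-20, and the
#' hinge-helix columns 51, 54, 55). Gaps at a requested column are
#' returned as \code{"-"}, not treated as errors; a column outside the
#' alignment frame is an error.
#'
#' @param x a \code{\linkS4class{DomainAlignment}} or a single aligned
#'   sequence (character scalar).
#' @param columns integer columns in the fixed frame.
#' @return for an alignment, a character matrix (rows = sequences, columns
#'   named by position); for a single sequence, a named character vector.
#' @export
recognitionResidues <- function(x,
                                columns = c(5, 15, 16, 17, 18, 19, 20,
                                            51, 54, 55)) {
  if (methods::is(x, "DomainAlignment")) {
    seqs <- alignedSeqs(x)
    w <- alignmentWidth(x)
    if (any(columns < 1L | columns > w))
      stop("requested column outside alignment frame (width ", w, ")")
    res <- vapply(columns, function(j) substr(seqs, j, j),
                  character(length(seqs)))
    res <- matrix(res, nrow = length(seqs),
                  dimnames = list(names(seqs), paste0("col", columns)))
    return(res)
  }
  stopifnot(is.character(x), length(x) == 1L)
  w <- nchar(x)
  if (any(columns < 1L | columns > w))
    stop("requested column outside alignment frame (width ", w, ")")
  stats::setNames(vapply(columns, function(j) substr(x, j, j), character(1)),
                  paste0("col", columns))
}

#' Partition aligned domains into recognition classes
#'
#' Restricts the alignment to sequences matching \code{restrict} at
#' \code{restrictCols} (default: T,V,S,R at recognition-helix columns
#' 17-20) and partitions the survivors by their residues at the
#' specificity columns (15, 16). Classes are returned in lexicographic
#' order of the recognition pair and together cover exactly the restricted
#' set.
#'
#' @param alignment a \code{\linkS4class{DomainAlignment}}.
#' @param restrict amino-acid string required at \code{restrictCols};
#'   \code{NULL} disables the restriction.
#' @param restrictCols alignment columns checked against \code{restrict}.
#' @param pairCols the two specificity columns defining the classes.
#' @return named list of classes; each element is a list with
#'   \code{aa_pair}, \code{members} (character ids) and
#'   \code{restriction}. Attribute \code{"classMap"} carries the flat
#'   data.frame (\code{tf_id}, \code{aa_pair}).
#' @export
partitionClasses <- function(alignment, restrict = "TVSR",
                             restrictCols = 17:20, pairCols = c(15, 16)) {
  stopifnot(methods::is(alignment, "DomainAlignment"))
  seqs <- alignedSeqs(alignment)
  if (!is.null(restrict)) {
    stopifnot(nchar(restrict) == length(restrictCols))
    helix <- vapply(restrictCols, function(j) substr(seqs, j, j),
                    character(length(seqs)))
    helix <- apply(matrix(helix, nrow = length(seqs)), 1, paste,
                   collapse = "")
    seqs <- seqs[helix == restrict]
  }
  if (length(seqs) == 0L) {
    out <- list()
    attr(out, "classMap") <- data.frame(tf_id = character(0),
                                        aa_pair = character(0),
                                        stringsAsFactors = FALSE)
    return(out)
  }
  pair <- paste0(substr(seqs, pairCols[1], pairCols[1]),
                 substr(seqs, pairCols[2], pairCols[2]))
  classes <- sort(unique(pair))
  out <- lapply(classes, function(cl) {
    list(aa_pair = cl, members = names(seqs)[pair == cl],
         restriction = if (is.null(restrict)) NA_character_ else restrict)
  })
  names(out) <- classes
  attr(out, "classMap") <- data.frame(tf_id = names(seqs), aa_pair = pair,
                                      stringsAsFactors = FALSE)
  out
}
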