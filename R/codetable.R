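# Per-class consensus sequences, the class-weighted consensus logo, the
# recognition-code table, and summary tallies.

#' Majority consensus of a site set
#'
#' Per-column majority base; ties are broken alphabetically among the
#' tied maxima and flagged in the \code{"ties"} attribute.
#'
#' @param sites character vector of equal-length sites (or a site table).
#' @return consensus sequence (character scalar) with attribute
#'   \code{"ties"} (logical per column).
#' @export
classConsensus <- function(sites) {
  if (is.data.frame(sites)) sites <- sites$sequence
  sites <- toupper(as.character(sites))
  stopifnot(length(sites) >= 1L)
  if (length(unique(nchar(sites))) != 1L) stop("ragged site set")
  m <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  cols <- apply(m, 2, function(col) {
    tab <- table(factor(col, levels = DNA_BASES))
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    c(base = sort(winners)[1], tie = length(winners) > 1L)
  })
  out <- paste(cols["base", ], collapse = "")
  attr(out, "ties") <- as.logical(cols["tie", ])
  out
}

#' Consensus logo over per-class consensus sequences
#'
#' Builds the logo from one consensus sequence per class, so every class
#' contributes equally regardless of how many sites it carries (this is
#' the point of the construction: heavily populated classes cannot
#' dominate the family-level picture).
#'
#' @param consensuses character vector of equal-length class consensuses.
#' @return list with \code{freq} and \code{ic} as in
#'   \code{\link{siteLogo}}.
#' @export
consensusLogo <- function(consensuses) {
  consensuses <- vapply(consensuses, as.character, character(1))
  if (length(unique(nchar(consensuses))) != 1L)
    stop("ragged consensus set (normalize inserted positions upstream)")
  siteLogo(unname(consensuses))
}

#' Assemble the recognition-code table
#'
#' Joins recognition classes, their final binding sites and their
#' degeneracy relations into one table: per class, the significant
#' palindromic (NT-5, NT-4) associations with counts, the relation
#' annotations, and the reporting triad (number of regulators in the
#' class, number with at least one site, total sites).
#'
#' @param classes class partition: the list from
#'   \code{\link{partitionClasses}} or a data.frame \code{tf_id},
#'   \code{aa_pair}.
#' @param sites site table with \code{tf_id} filled; every referenced
#'   regulator must belong to a class.
#' @param relations optional named list (by \code{aa_pair}) of relation
#'   data.frames; computed with \code{\link{classifyDegeneracies}} when
#'   \code{NULL}.
#' @param backgroundDinuc,alphaFdr significance parameters
#'   (see \code{\link{significantCombinations}}).
#' @return data.frame of class \code{"CodeTable"}, rows sorted by
#'   \code{aa_pair}: \code{aa_pair}, \code{associations} (e.g.
#'   \code{"TG:12"}, \code{";"}-separated), \code{relations} (arrow
#'   strings), \code{n_tfs}, \code{n_tfs_with_bs}, \code{n_bs}. The
#'   per-class relation tables are attached as attribute
#'   \code{"relations"}.
#' @export
assembleCodeTable <- function(classes, sites, relations = NULL,
                              backgroundDinuc = backgroundDinucleotides(),
                              alphaFdr = 0.05) {
  if (is.data.frame(classes)) {
    classMap <- classes
  } else {
    classMap <- attr(classes, "classMap")
    if (is.null(classMap))
      classMap <- do.call(rbind, lapply(classes, function(cl)
        data.frame(tf_id = cl$members, aa_pair = cl$aa_pair,
                   stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("tf_id", "aa_pair") %in% names(classMap)))
  if (nrow(sites)) {
    unknown <- setdiff(unique(sites$tf_id), classMap$tf_id)
    if (length(unknown))
      stop("sites reference regulators missing from the classes: ",
           paste(unknown, collapse = ", "))
  }
  aaPairs <- sort(unique(classMap$aa_pair))
  relOut <- list()
  rows <- lapply(aaPairs, function(cls) {
    members <- classMap$tf_id[classMap$aa_pair == cls]
    clSites <- sites[sites$tf_id %in% members, , drop = FALSE]
    nBs <- nrow(clSites)
    nWith <- length(unique(clSites$tf_id))
    assoc <- ""
    relStr <- ""
    if (nBs > 0L) {
      F <- buildCombinationMatrix(clSites$sequence)
      S <- significantCombinations(F, backgroundDinuc, alphaFdr)
      sigPal <- S[S$significant & S$palindromic, , drop = FALSE]
      if (nrow(sigPal))
        assoc <- paste(sprintf("%s:%d", sigPal$left, sigPal$count),
                       collapse = ";")
      rel <- if (!is.null(relations)) {
        if (is.null(relations[[cls]]))
          classifyDegeneracies(S, F, alphaFdr) else relations[[cls]]
      } else classifyDegeneracies(S, F, alphaFdr)
      relOut[[cls]] <<- rel
      if (nrow(rel))
        relStr <- paste(sprintf("%s%s%s", rel$semiseq_a, rel$direction,
                                rel$semiseq_b), collapse = ";")
    }
    data.frame(aa_pair = cls, associations = assoc, relations = relStr,
               n_tfs = length(members), n_tfs_with_bs = nWith,
               n_bs = nBs, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    out <- data.frame(aa_pair = character(0), associations = character(0),
                      relations = character(0), n_tfs = integer(0),
                      n_tfs_with_bs = integer(0), n_bs = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "relations") <- relOut
  class(out) <- c("CodeTable", "data.frame")
  out
}

#' Summary tallies of a code table
#'
#' @param codeTable table from \code{\link{assembleCodeTable}}.
#' @return named numeric vector: \code{n_classes},
#'   \code{n_classes_with_bs}, \code{n_intrinsic} (symmetric plus
#'   asymmetric relations), \code{n_extrinsic}, \code{n_tfs_with_bs},
#'   \code{n_bs_total}.
#' @export
summarizeCodeTable <- function(codeTable) {
  rels <- attr(codeTable, "relations")
  nInt <- 0L; nExt <- 0L
  if (!is.null(rels)) {
    for (rel in rels) {
      if (is.null(rel) || !nrow(rel)) next
      nInt <- nInt + sum(rel$type %in% c("sym_intrinsic", "asym_intrinsic"))
      nExt <- nExt + sum(rel$type == "extrinsic")
    }
  }
  c(n_classes = nrow(codeTable),
    n_classes_with_bs = sum(codeTable$n_bs > 0),
    n_intrinsic = nInt,
    n_extrinsic = nExt,
    n_tfs_with_bs = sum(codeTable$n_tfs_with_bs),
    n_bs_total = sum(codeTable$n_bs))
}

#' Write a code table as TSV
#'
#' @param codeTable table from \code{\link{assembleCodeTable}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeCodeTable <- function(codeTable, path) {
  write.table(as.data.frame(codeTable), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
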