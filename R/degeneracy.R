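# Half-site quartet extraction and classification of binding-site sets
# into intrinsic (symmetric/asymmetric) and extrinsic degeneracies via the
# combination (F) and significance (S) matrices.

#' Specificity quartet of a 14-bp site
#'
#' Reads the four specificity bases of a site: (NT-5, NT-4) of the left
#' half site on the sense strand, and the mirror positions of the right
#' half site read on the complementary strand, reduced to an unordered
#' pair of dinucleotides. A perfect palindrome has equal left and right
#' semisequences; a site and its reverse complement give the same quartet.
#'
#' @param site 14-bp site sequence. 15-bp sites carrying the extra central
#'   base must be normalized first with \code{\link{dropCentralInsertion}}.
#' @return list with \code{left}, \code{right} (dinucleotides as read),
#'   \code{pair} (the unordered pair, sorted), and \code{palindromic}.
#' @examples
#' siteQuartet("TGTGAACGTTCACA")$pair
#' @export
siteQuartet <- function(site) {
  site <- toupper(site)
  if (nchar(site) != 14L)
    stop("site must be 14 bp after normalization, got ", nchar(site))
  left <- substr(site, 3L, 4L)                 # NT-5, NT-4 of left half
  right <- revComp(substr(site, 11L, 12L))     # mirror positions, c strand
  pair <- sort(c(left, right))
  list(left = left, right = right, pair = pair,
       palindromic = left == right)
}

#' Drop the extra central base of a 15-bp asymmetric site
#'
#' Some natural operators carry one inserted base between the half sites;
#' it is removed (position 8 of 15) before quartet extraction, yielding the
#' canonical 14-bp frame.
#'
#' @param site 15-bp site sequence (14-bp input is returned unchanged).
#' @return 14-bp site sequence.
#' @export
dropCentralInsertion <- function(site) {
  n <- nchar(site)
  if (n == 14L) return(site)
  if (n != 15L) stop("expected a 14- or 15-bp site, got ", n, " bp")
  paste0(substr(site, 1L, 7L), substr(site, 9L, 15L))
}

#' All unordered dinucleotide-pair combinations
#'
#' Enumerates the unordered pairs of the 16 dinucleotides: 16 palindromic
#' (diagonal) plus 120 mixed cells, 136 in total. Cell keys are
#' \code{"XX|YY"} with the two dinucleotides sorted.
#'
#' @return character vector of 136 cell keys.
#' @export
quartetCombinations <- function() {
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES,
                            function(a, b) paste0(a, b)))
  dinucs <- sort(dinucs)
  keys <- character(0)
  for (i in seq_along(dinucs))
    for (j in i:length(dinucs))
      keys <- c(keys, paste(dinucs[i], dinucs[j], sep = "|"))
  keys
}

.quartetKey <- function(left, right) {
  ifelse(left <= right, paste(left, right, sep = "|"),
         paste(right, left, sep = "|"))
}

#' Triangular combination-count matrix F
#'
#' Counts, over a binding-site set, how many sites fall into each of the
#' 136 unordered dinucleotide-pair cells; every site contributes exactly
#' one count, so the cell sum equals the number of sites.
#'
#' @param sites character vector of 14-bp sites (or a site table).
#' @return named integer vector over the 136 cell keys with attribute
#'   \code{"total"}.
#' @export
buildCombinationMatrix <- function(sites) {
  if (is.data.frame(sites)) sites <- sites$sequence
  sites <- toupper(as.character(sites))
  stopifnot(length(sites) >= 1L)
  keys <- vapply(sites, function(s) {
    q <- siteQuartet(s)
    .quartetKey(q$left, q$right)
  }, character(1), USE.NAMES = FALSE)
  all <- quartetCombinations()
  counts <- table(factor(keys, levels = all))
  out <- stats::setNames(as.integer(counts), all)
  attr(out, "total") <- length(sites)
  out
}

# Expected cell probability under independent background half sites:
# 2 q_a q_b for mixed cells, q_a^2 for palindromic cells.
.cellProbs <- function(backgroundDinuc) {
  dinucs <- sort(names(backgroundDinuc))
  keys <- quartetCombinations()
  parts <- strsplit(keys, "|", fixed = TRUE)
  p <- vapply(parts, function(ab) {
    qa <- backgroundDinuc[[ab[1]]]
    qb <- backgroundDinuc[[ab[2]]]
    if (ab[1] == ab[2]) qa^2 else 2 * qa * qb
  }, numeric(1))
  stats::setNames(p, keys)
}

#' Uniform (or custom) background dinucleotide probabilities
#'
#' @param baseProbs length-4 base probabilities (A,C,G,T); dinucleotide
#'   probabilities are their products.
#' @return named length-16 probability vector over the dinucleotides.
#' @export
backgroundDinucleotides <- function(baseProbs = rep(0.25, 4)) {
  stopifnot(length(baseProbs) == 4L, abs(sum(baseProbs) - 1) < 1e-8)
  p <- as.vector(outer(baseProbs, baseProbs))
  names(p) <- as.vector(outer(DNA_BASES, DNA_BASES,
                              function(a, b) paste0(a, b)))
  p[order(names(p))]
}

#' Significant combination cells (matrix S)
#'
#' Tests every F cell for over-representation against the background
#' expectation with a binomial upper-tail test and controls the false
#' discovery rate with Benjamini-Hochberg across the 136 cells. Surviving
#' cells form the S matrix.
#'
#' @param F combination counts from \code{\link{buildCombinationMatrix}}.
#' @param backgroundDinuc named length-16 dinucleotide probabilities
#'   (summing to 1).
#' @param alphaFdr FDR level.
#' @return data.frame with one row per cell: \code{combo}, \code{left},
#'   \code{right}, \code{count}, \code{prob0}, \code{p}, \code{padj},
#'   \code{significant}, \code{palindromic}; attribute \code{"total"}
#'   carries the site count.
#' @export
significantCombinations <- function(F,
                                    backgroundDinuc =
                                      backgroundDinucleotides(),
                                    alphaFdr = 0.05) {
  stopifnot(abs(sum(backgroundDinuc) - 1) < 1e-8)
  n <- attr(F, "total")
  if (is.null(n)) n <- sum(F)
  p0 <- .cellProbs(backgroundDinuc)[names(F)]
  pvals <- pbinom(as.numeric(F) - 1, n, p0, lower.tail = FALSE)
  pvals[F == 0] <- 1
  padj <- p.adjust(pvals, method = "BH")
  parts <- strsplit(names(F), "|", fixed = TRUE)
  out <- data.frame(
    combo = names(F),
    left = vapply(parts, `[`, character(1), 1L),
    right = vapply(parts, `[`, character(1), 2L),
    count = as.integer(F),
    prob0 = unname(p0),
    p = unname(pvals),
    padj = unname(padj),
    significant = unname(padj < alphaFdr & F > 0),
    stringsAsFactors = FALSE)
  out$palindromic <- out$left == out$right
  attr(out, "total") <- n
  out
}

#' Classify degeneracies of a binding-site set
#'
#' Resolves the S matrix of a recognition class into degeneracy relations:
#' \enumerate{
#'   \item For every pair of significant palindromic cells, the expected
#'     mixture count under independent half-site pairing is
#'     \code{2 r_a r_b n}, with half-site frequencies \code{r} estimated
#'     from palindrome counts only. Mixtures significantly below that
#'     expectation (binomial lower tail, BH at the same FDR) mark an
#'     extrinsic degeneracy between the two semisequences.
#'   \item Extrinsic relations partition the semisequences into blocks
#'     (connected components of the significant non-extrinsic cells).
#'   \item Within a block spanning at least two semisequences, a
#'     palindrome whose count significantly exceeds the block's uniform
#'     expectation makes the recognition asymmetric with that dominant
#'     palindrome (relations minor to dominant); otherwise the block is a
#'     symmetric intrinsic degeneracy among its palindromes.
#' }
#'
#' @param S data.frame from \code{\link{significantCombinations}}.
#' @param F combination counts from \code{\link{buildCombinationMatrix}}
#'   (defaults to the counts stored in \code{S}).
#' @param alphaFdr FDR level shared by the under-representation and
#'   dominance tests.
#' @return data.frame of relations: \code{type}
#'   (\code{sym_intrinsic}, \code{asym_intrinsic}, \code{extrinsic}),
#'   \code{semiseq_a}, \code{semiseq_b}, \code{direction} (arrow string;
#'   \code{a->b} runs minor to dominant), \code{p_value}. Zero rows when
#'   no degeneracy is resolved.
#' @export
classifyDegeneracies <- function(S, F = NULL, alphaFdr = 0.05) {
  if (nrow(S) == 0L) stop("S matrix is empty")
  n <- attr(S, "total")
  counts <- stats::setNames(S$count, S$combo)
  sig <- S[S$significant, , drop = FALSE]
  emptyRel <- data.frame(type = character(0), semiseq_a = character(0),
                         semiseq_b = character(0), direction = character(0),
                         p_value = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(emptyRel)

  palCount <- function(a) counts[[paste(a, a, sep = "|")]]
  mixCount <- function(a, b) counts[[.quartetKey(a, b)]]

  sigPal <- sort(unique(sig$left[sig$palindromic]))
  relations <- list()

  ## 1) extrinsic: significantly under-represented mixtures between
  ##    significant palindromes
  extPairs <- list()
  if (length(sigPal) >= 2L) {
    allPal <- sum(vapply(unique(c(S$left, S$right)), palCount, numeric(1)))
    pairs <- utils::combn(sigPal, 2L)
    pLow <- apply(pairs, 2L, function(ab) {
      ra <- palCount(ab[1]) / allPal
      rb <- palCount(ab[2]) / allPal
      pbinom(mixCount(ab[1], ab[2]), n, 2 * ra * rb)
    })
    padjLow <- p.adjust(pLow, method = "BH")
    for (k in seq_len(ncol(pairs))) {
      if (!is.na(padjLow[k]) && padjLow[k] < alphaFdr) {
        extPairs[[length(extPairs) + 1L]] <- pairs[, k]
        relations[[length(relations) + 1L]] <- data.frame(
          type = "extrinsic", semiseq_a = pairs[1, k],
          semiseq_b = pairs[2, k], direction = ">-<",
          p_value = pLow[k], stringsAsFactors = FALSE)
      }
    }
  }
  isExtrinsic <- function(a, b)
    any(vapply(extPairs, function(pp) all(sort(pp) == sort(c(a, b))),
               logical(1)))

  ## 2) blocks: connected components over semisequences of significant
  ##    cells, with extrinsic pairs disconnected
  nodes <- sort(unique(c(sig$left, sig$right)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(sig))) {
    a <- sig$left[r]; b <- sig$right[r]
    if (a != b && !isExtrinsic(a, b)) {
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  blocks <- list()
  seen <- character(0)
  for (v in nodes) {
    if (v %in% seen) next
    comp <- v; queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- setdiff(adj[[u]], comp)
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    blocks[[length(blocks) + 1L]] <- comp
  }

  ## 3) within-block dominance: asymmetric vs symmetric intrinsic
  domTests <- list()
  for (bi in seq_along(blocks)) {
    B <- blocks[[bi]]
    if (length(B) < 2L) next
    palB <- vapply(B, palCount, numeric(1))
    npal <- sum(palB)
    if (npal == 0) next
    top <- names(palB)[which.max(palB)]
    # Bonferroni over which palindrome is the candidate dominant: the
    # statistic is the block maximum, so the naive tail is inflated k-fold
    pDom <- min(1, length(B) *
                  pbinom(max(palB) - 1, npal, 1 / length(B),
                         lower.tail = FALSE))
    domTests[[length(domTests) + 1L]] <-
      list(block = bi, dominant = top, p = pDom)
  }
  if (length(domTests)) {
    pAdjDom <- p.adjust(vapply(domTests, `[[`, numeric(1), "p"),
                        method = "BH")
    for (k in seq_along(domTests)) {
      dt <- domTests[[k]]
      B <- blocks[[dt$block]]
      if (pAdjDom[k] < alphaFdr) {
        for (minor in setdiff(B, dt$dominant)) {
          if (isExtrinsic(minor, dt$dominant)) next
          relations[[length(relations) + 1L]] <- data.frame(
            type = "asym_intrinsic", semiseq_a = minor,
            semiseq_b = dt$dominant, direction = "->",
            p_value = dt$p, stringsAsFactors = FALSE)
        }
      } else {
        prs <- utils::combn(B, 2L)
        for (j in seq_len(ncol(prs))) {
          if (isExtrinsic(prs[1, j], prs[2, j])) next
          relations[[length(relations) + 1L]] <- data.frame(
            type = "sym_intrinsic", semiseq_a = prs[1, j],
            semiseq_b = prs[2, j], direction = "<->",
            p_value = dt$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(relations)) return(emptyRel)
  out <- do.call(rbind, relations)
  rownames(out) <- NULL
  out
}

#' Scenario label from a relation set
#'
#' Collapses the relations of one class to a single label for benchmark
#' scoring: \code{"extrinsic"} if any extrinsic relation is present, else
#' \code{"asym_intrinsic"}, else \code{"sym_intrinsic"}, else
#' \code{"none"}.
#'
#' @param relations data.frame from \code{\link{classifyDegeneracies}}.
#' @return character scalar.
#' @export
scenarioLabel <- function(relations) {
  if (nrow(relations) == 0L) return("none")
  if (any(relations$type == "extrinsic")) return("extrinsic")
  if (any(relations$type == "asym_intrinsic")) return("asym_intrinsic")
  if (any(relations$type == "sym_intrinsic")) return("sym_intrinsic")
  "none"
}
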