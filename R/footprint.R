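# First binding-site scan per recognition class: a palindromic Gibbs motif
# sampler with zero-or-one occupancy per region, run over pooled strict
# intergenic regions.

#' Configuration for the palindromic Gibbs site scan
#'
#' Bundles the sampler parameters. The motif model is palindrome-
#' constrained (count matrix averaged with its reverse complement at every
#' update) and each region carries at most one site. Occupancy follows the
#' site-sampler parameterization: each window carries a prior probability
#' \code{expectedSites / total windows} of starting a site (so the
#' expected site total over all regions equals \code{expectedSites}, by
#' default the number of regions), truncated to zero-or-one occupancy per
#' region, which keeps site absence reachable.
#'
#' @param width motif width in bp (even when palindromic).
#' @param palindromic constrain the motif model to its reverse complement.
#' @param expectedSites expected total site count; \code{NULL} means the
#'   number of regions searched.
#' @param background length-4 base probabilities.
#' @param confidenceCutoff minimum sampling confidence for a reported site
#'   (in (0, 1]).
#' @param nChains,iters,burnIn sampler schedule (chains are pooled).
#' @param pseudoTotal Dirichlet pseudo-observations per motif column.
#' @param seed integer seed (mandatory).
#' @return a validated list of class \code{"GibbsConfig"}.
#' @export
gibbsConfig <- function(width = 14L, palindromic = TRUE,
                        expectedSites = NULL, background = rep(0.25, 4),
                        confidenceCutoff = 0.40, nChains = 5L,
                        iters = 2000L, burnIn = 500L, pseudoTotal = 1,
                        seed) {
  stopifnot(width >= 2L, confidenceCutoff > 0, confidenceCutoff <= 1,
            nChains >= 1L, iters > burnIn, burnIn >= 0L,
            abs(sum(background) - 1) < 1e-8)
  if (palindromic && width %% 2L != 0L)
    stop("palindromic motifs require an even width")
  structure(list(width = as.integer(width), palindromic = palindromic,
                 expectedSites = expectedSites, background = background,
                 confidenceCutoff = confidenceCutoff,
                 nChains = as.integer(nChains), iters = as.integer(iters),
                 burnIn = as.integer(burnIn), pseudoTotal = pseudoTotal,
                 seed = .checkSeed(seed)),
            class = "GibbsConfig")
}

#' Palindromic Gibbs search for one site per region
#'
#' Runs \code{nChains} independent Gibbs chains over the pooled regions.
#' Each sweep resamples, for every region, either no site or one window
#' start from the predictive distribution under the current palindromic
#' motif model. Post-burn-in samples are pooled across chains; a region's
#' reported start is the modal sampled start (leftmost on ties) and its
#' confidence is the fraction of pooled samples placing a site within
#' 2 bp of that start. Sites below \code{confidenceCutoff} are discarded.
#'
#' @param regions named character vector or \code{DNAStringSet} of strict
#'   intergenic regions (at least 2; regions shorter than the motif width
#'   are skipped with a warning).
#' @param config a \code{\link{gibbsConfig}}.
#' @param tfMap optional named character vector mapping region id to
#'   regulator id; by default a trailing \code{_up}/\code{_down} suffix is
#'   stripped from the region id.
#' @return a site table (see \code{\link{emptySiteTable}}) with
#'   confidences and log-odds scores under the motif built from the
#'   reported sites; the occupancy fraction per region is attached as
#'   attribute \code{"occupancy"}.
#' @export
gibbsSearch <- function(regions, config, tfMap = NULL) {
  stopifnot(inherits(config, "GibbsConfig"))
  regions <- .asSeqVector(regions, "regions")
  w <- config$width
  short <- nchar(regions) < w
  if (any(short)) {
    warning("skipping ", sum(short), " region(s) shorter than the motif width")
    regions <- regions[!short]
  }
  if (length(regions) < 2L)
    stop("need at least 2 regions of usable length")
  n <- length(regions)
  expected <- if (is.null(config$expectedSites)) n else config$expectedSites
  totalWindows <- sum(nchar(regions) - w + 1L)
  piW <- min(max(expected / totalWindows, 1e-9), 0.5)
  logOccOdds <- log(piW / (1 - piW))
  codes0 <- lapply(regions, function(s) .seqCodes(s) - 1L)  # 0-based, NA -> bad
  codes0 <- lapply(codes0, function(v) { v[is.na(v)] <- -1L; v })

  set.seed(config$seed)
  samples <- do.call(rbind, lapply(seq_len(config$nChains), function(ch) {
    .gibbsChain(codes0, w, config$iters, config$burnIn,
                config$background, config$pseudoTotal, logOccOdds,
                config$palindromic)
  }))

  nSamp <- nrow(samples)
  occupancy <- colMeans(samples > 0)
  rows <- list()
  for (i in seq_len(n)) {
    occ <- samples[, i]
    occ <- occ[occ > 0]
    if (!length(occ)) next
    tab <- tabulate(occ)
    start1 <- which.max(tab)                      # leftmost modal start
    conf <- sum(samples[, i] >= start1 - 2L &
                  samples[, i] <= start1 + 2L & samples[, i] > 0L) / nSamp
    if (conf < config$confidenceCutoff) next
    rid <- names(regions)[i]
    rows[[length(rows) + 1L]] <- data.frame(
      tf_id = NA_character_, region_id = rid,
      start = start1 - 1L, end = start1 - 1L + w, strand = "+",
      sequence = .slice(regions[[i]], start1 - 1L, start1 - 1L + w),
      score = NA_real_, zscore = NA_real_, confidence = conf,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else emptySiteTable()
  if (nrow(sites)) {
    if (is.null(tfMap))
      tfMap <- stats::setNames(sub("_(up|down)$", "", names(regions)),
                               names(regions))
    sites$tf_id <- unname(tfMap[sites$region_id])
    pwm <- buildPWM(sites$sequence, pseudocount = 1,
                    background = config$background,
                    palindromic = config$palindromic)
    lo <- pwmLogOdds(pwm)
    sites$score <- vapply(sites$sequence, function(s)
      sum(lo[cbind(.seqCodes(s), seq_len(w))]), numeric(1),
      USE.NAMES = FALSE)
  }
  attr(sites, "occupancy") <- occupancy
  .validateSiteTable(sites)
  sites
}

#' Per-column information content of a site alignment
#'
#' Sequence-logo statistics: per-column base frequencies and information
#' content \eqn{IC_j = 2 + \sum_b f_{bj} \log_2 f_{bj}} (plug-in, no
#' small-sample correction).
#'
#' @param sites character vector of equal-length sites, or a site table
#'   (its \code{sequence} column is used).
#' @return list with \code{freq} (4 x width matrix, rows A,C,G,T) and
#'   \code{ic} (per-column bits, in [0, 2]).
#' @examples
#' siteLogo(c("ACGT", "ACGT"))$ic  # 2 bits everywhere
#' @export
siteLogo <- function(sites) {
  if (is.data.frame(sites)) sites <- sites$sequence
  sites <- toupper(as.character(sites))
  stopifnot(length(sites) >= 1L)
  if (length(unique(nchar(sites))) != 1L)
    stop("ragged site set")
  w <- nchar(sites[1])
  m <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  freq <- vapply(seq_len(w), function(j) {
    tab <- table(factor(m[, j], levels = DNA_BASES))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(freq) <- DNA_BASES
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  list(freq = freq, ic = ic)
}
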