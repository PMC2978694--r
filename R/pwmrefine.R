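# Second binding-site search: iterative PWM construction, candidate
# scanning over extended regions, empirical-null p-value selection,
# convergence, and Z-scores.

#' Build a pseudocounted PWM from aligned sites
#'
#' Counts bases per position and smooths with a constant pseudocount:
#' cell frequency \code{(count + B/4) / (N + B)}. With
#' \code{palindromic = TRUE} the count matrix is averaged with its reverse
#' complement before storage, so it equals its own reverse complement.
#'
#' @param sites character vector of equal-width sites (or a site table).
#' @param pseudocount constant B (total pseudo-observations per column).
#' @param background length-4 base probabilities.
#' @param palindromic enforce the palindromic constraint.
#' @return a \code{\linkS4class{RecognitionPWM}}.
#' @examples
#' pwm <- buildPWM(c("TGTGACGTCACA", "TGTGACGTCACA"), pseudocount = 1)
#' pwmWidth(pwm)
#' @export
buildPWM <- function(sites, pseudocount = 1, background = rep(0.25, 4),
                     palindromic = FALSE) {
  if (is.data.frame(sites)) sites <- sites$sequence
  sites <- toupper(as.character(sites))
  if (length(sites) < 1L) stop("need at least one site")
  if (length(unique(nchar(sites))) != 1L)
    stop("width mismatch among sites")
  w <- nchar(sites[1])
  m <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j)
    as.numeric(table(factor(m[, j], levels = DNA_BASES))), numeric(4))
  rownames(counts) <- DNA_BASES
  if (palindromic) counts <- (counts + .revCompMatrix(counts)) / 2
  methods::new("RecognitionPWM", counts = counts,
               pseudocount = pseudocount, background = background,
               palindromic = palindromic)
}

#' Slide a PWM over regions and report scoring windows
#'
#' Scores every window of every region with the base-2 log-odds of the
#' PWM and reports those at or above \code{minScore}. Both strands are
#' considered; a palindromic PWM scores both strands identically, so its
#' hits are collapsed to the sense strand. Windows containing ambiguous
#' bases score \code{-Inf} and are never reported (unless
#' \code{minScore = -Inf}, in which case every finite-scoring window is).
#'
#' @param pwm a \code{\linkS4class{RecognitionPWM}}.
#' @param regions named character vector or \code{DNAStringSet}; each
#'   region must be at least as long as the PWM.
#' @param minScore score threshold (default \code{-Inf}: all windows).
#' @param tfMap optional region-to-regulator map (see
#'   \code{\link{gibbsSearch}}).
#' @return a candidate site table sorted by (region, start, strand).
#' @export
scanPWM <- function(pwm, regions, minScore = -Inf, tfMap = NULL) {
  stopifnot(methods::is(pwm, "RecognitionPWM"))
  regions <- .asSeqVector(regions, "regions")
  w <- pwmWidth(pwm)
  if (any(nchar(regions) < w))
    stop("region shorter than PWM width")
  lo <- pwmLogOdds(pwm)
  loRC <- .revCompMatrix(lo)
  pal <- max(abs(lo - loRC)) < 1e-9
  if (is.null(tfMap))
    tfMap <- stats::setNames(sub("_(up|down)$", "", names(regions)),
                             names(regions))
  out <- list()
  for (rid in names(regions)) {
    codes <- .seqCodes(regions[[rid]])
    sSense <- .windowScores(lo, codes, w)
    keep <- which(sSense >= minScore & is.finite(sSense))
    if (length(keep)) {
      starts <- keep - 1L
      out[[length(out) + 1L]] <- data.frame(
        tf_id = unname(tfMap[rid]), region_id = rid,
        start = starts, end = starts + w, strand = "+",
        sequence = substring(regions[[rid]], keep, keep + w - 1L),
        score = sSense[keep], zscore = NA_real_, confidence = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (!pal) {
      sAnti <- .windowScores(loRC, codes, w)
      keep <- which(sAnti >= minScore & is.finite(sAnti))
      if (length(keep)) {
        starts <- keep - 1L
        out[[length(out) + 1L]] <- data.frame(
          tf_id = unname(tfMap[rid]), region_id = rid,
          start = starts, end = starts + w, strand = "-",
          sequence = revComp(substring(regions[[rid]], keep, keep + w - 1L)),
          score = sAnti[keep], zscore = NA_real_, confidence = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else emptySiteTable()
  sites <- sites[order(sites$region_id, sites$start, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  .validateSiteTable(sites)
  sites
}

#' Empirical null score distribution from shuffled regions
#'
#' Mononucleotide-shuffles every region (composition preserved per
#' region), scans all windows with the PWM, and repeats with fresh
#' shuffles until at least \code{nNull} scores are collected; the first
#' \code{nNull} are kept. Deterministic given the seed.
#'
#' @param pwm a \code{\linkS4class{RecognitionPWM}}.
#' @param regions named character vector or \code{DNAStringSet}.
#' @param nNull null size (>= 1000).
#' @param seed integer seed.
#' @return list of class \code{"NullDistribution"} with \code{scores},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
nullScores <- function(pwm, regions, nNull = 1e5, seed) {
  stopifnot(methods::is(pwm, "RecognitionPWM"), nNull >= 1000)
  regions <- .asSeqVector(regions, "regions")
  w <- pwmWidth(pwm)
  usable <- regions[nchar(regions) >= w]
  if (!length(usable)) stop("no region long enough to scan")
  lo <- pwmLogOdds(pwm)
  loRC <- .revCompMatrix(lo)
  pal <- max(abs(lo - loRC)) < 1e-9
  set.seed(.checkSeed(seed))
  scores <- numeric(0)
  while (length(scores) < nNull) {
    for (s in usable) {
      sh <- shuffleRegion(s)
      codes <- .seqCodes(sh)
      v <- .windowScores(lo, codes, w)
      if (!pal) v <- c(v, .windowScores(loRC, codes, w))
      scores <- c(scores, v[is.finite(v)])
    }
  }
  scores <- scores[seq_len(nNull)]
  structure(list(scores = scores, mean = mean(scores), sd = sd(scores),
                 n = as.integer(nNull)),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution: n = %d, mean = %.3f, sd = %.3f\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Add-one empirical p-values against a null distribution
#'
#' \code{p = (1 + #\{null >= s\}) / (1 + n)}; never exactly zero.
#'
#' @param scores numeric scores.
#' @param null a \code{"NullDistribution"} (or numeric vector of null
#'   scores).
#' @return numeric p-values in (0, 1].
#' @export
empiricalP <- function(scores, null) {
  ns <- if (inherits(null, "NullDistribution")) null$scores else null
  nsSorted <- sort(ns)
  n <- length(nsSorted)
  # #\{null >= s\} via binary search on the sorted null
  geq <- n - findInterval(scores - 1e-12, nsSorted)
  (1 + geq) / (1 + n)
}

# Greedy best-score-first resolution of overlapping sites within a region:
# a site is suppressed when it overlaps an already-accepted site on the
# same region by >= minOverlap fraction of the site width.
.resolveOverlaps <- function(sites, minOverlap = 0.5) {
  if (nrow(sites) < 2L) return(sites)
  keep <- logical(nrow(sites))
  ord <- order(-sites$score, sites$region_id, sites$start)
  for (i in ord) {
    acc <- which(keep & sites$region_id == sites$region_id[i])
    ov <- FALSE
    for (j in acc) {
      inter <- min(sites$end[i], sites$end[j]) -
        max(sites$start[i], sites$start[j])
      if (inter >= minOverlap * (sites$end[i] - sites$start[i])) {
        ov <- TRUE
        break
      }
    }
    if (!ov) keep[i] <- TRUE
  }
  out <- sites[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative PWM refinement against an empirical null
#'
#' Starting from seed sites (typically the Gibbs-scan survivors), builds a
#' pseudocounted PWM, scans the extended regions for all candidate windows
#' scoring at least the minimum seed-site score (held fixed across
#' iterations), and then iterates: (i) draw an empirical null from the
#' current PWM over shuffled regions; (ii) keep candidates with empirical
#' p-value below \code{alpha}; (iii) resolve overlapping survivors
#' best-score-first; (iv) rebuild the PWM from the kept set and rescore
#' all candidates. Iteration stops when the kept set repeats or
#' \code{maxIter} is reached. Multiple sites per region and sites in the
#' coding extension are allowed. Final sites carry Z-scores against the
#' final null.
#'
#' @param seedSites site table (or character sites) from the first scan.
#' @param regions extended regions (named character or \code{DNAStringSet}).
#' @param pseudocount,background,palindromic PWM parameters
#'   (see \code{\link{buildPWM}}).
#' @param nNull null size per iteration.
#' @param alpha empirical p-value cutoff.
#' @param maxIter iteration cap.
#' @param minOverlap overlap fraction above which the weaker of two
#'   overlapping sites is suppressed.
#' @param seed integer seed.
#' @param sitePredicate optional post-filter hook: a function taking the
#'   kept site table and returning a logical keep vector, applied after
#'   each selection step (default none).
#' @return list with \code{sites} (final site table with Z-scores),
#'   \code{pwm}, \code{nIterations}, \code{trace} (kept-set size per
#'   iteration) and \code{null} (final \code{"NullDistribution"}).
#' @export
refineSites <- function(seedSites, regions, pseudocount = 1,
                        background = rep(0.25, 4), palindromic = TRUE,
                        nNull = 1e5, alpha = 1e-3, maxIter = 50L,
                        minOverlap = 0.5, seed, sitePredicate = NULL) {
  seedSeqs <- if (is.data.frame(seedSites)) seedSites$sequence else
    as.character(seedSites)
  if (!length(seedSeqs)) stop("seed site set is empty")
  regions <- .asSeqVector(regions, "regions")
  seed <- .checkSeed(seed)
  w <- nchar(seedSeqs[1])

  pwm <- buildPWM(seedSeqs, pseudocount, background, palindromic)
  lo <- pwmLogOdds(pwm)
  seedScores <- vapply(seedSeqs, function(s)
    sum(lo[cbind(.seqCodes(s), seq_len(w))]), numeric(1), USE.NAMES = FALSE)
  minScore <- min(seedScores)

  # small slack so the weakest seed site itself cannot fall out of the
  # candidate set through floating-point summation order
  candidates <- scanPWM(pwm, regions, minScore - 1e-9)
  if (nrow(candidates) == 0L) {
    warning("no candidates at the seed minimum score; empty result")
    return(list(sites = emptySiteTable(), pwm = pwm, nIterations = 0L,
                trace = integer(0), null = NULL))
  }
  candKey <- function(df) paste(df$region_id, df$start, df$strand)

  keptKey <- character(0)
  trace <- integer(0)
  nIter <- 0L
  null <- NULL
  kept <- candidates
  repeat {
    nIter <- nIter + 1L
    null <- nullScores(pwm, regions, nNull, seed = .subSeed(seed, nIter))
    p <- empiricalP(candidates$score, null)
    kept <- candidates[p < alpha, , drop = FALSE]
    kept <- .resolveOverlaps(kept, minOverlap)
    if (!is.null(sitePredicate) && nrow(kept))
      kept <- kept[sitePredicate(kept), , drop = FALSE]
    trace <- c(trace, nrow(kept))
    if (nrow(kept) == 0L) {
      warning("kept-site set became empty during refinement")
      return(list(sites = emptySiteTable(), pwm = pwm, nIterations = nIter,
                  trace = trace, null = null))
    }
    newKey <- sort(candKey(kept))
    if (identical(newKey, keptKey) || nIter >= maxIter) break
    keptKey <- newKey
    pwm <- buildPWM(kept$sequence, pseudocount, background, palindromic)
    lo <- pwmLogOdds(pwm)
    candidates$score <- vapply(candidates$sequence, function(s)
      sum(lo[cbind(.seqCodes(s), seq_len(w))]), numeric(1),
      USE.NAMES = FALSE)
  }
  kept$zscore <- (kept$score - null$mean) / null$sd
  rownames(kept) <- NULL
  list(sites = kept, pwm = pwm, nIterations = nIter, trace = trace,
       null = null)
}

#' Filter sites by Z-score
#'
#' @param sites site table carrying a \code{zscore} column.
#' @param zMin minimum Z-score kept.
#' @return filtered site table.
#' @export
zscoreFilter <- function(sites, zMin = 4) {
  stopifnot("zscore" %in% names(sites))
  out <- sites[!is.na(sites$zscore) & sites$zscore >= zMin | zMin == -Inf, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
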