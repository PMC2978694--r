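# Synthetic families, intergenic regions with planted operators, and
# degeneracy benchmark sets. The generator is the ground truth against
# which every downstream stage is benchmarked.

# Half-site backbone, outer (NT-7) to inner (NT-1): T G <s1> <s2> A <var> C.
# NT-6 (G) and NT-1 (C, half of the central CG) are fully conserved; NT-7
# and NT-3 match the backbone with probability `identity`; NT-2 is free.
.makeHalfSite <- function(semiseq, identity) {
  s <- strsplit(semiseq, "", fixed = TRUE)[[1]]
  noisy <- function(b) {
    if (runif(1) < identity) b else sample(setdiff(DNA_BASES, b), 1L)
  }
  paste0(noisy("T"), "G", s[1], s[2], noisy("A"),
         sample(DNA_BASES, 1L), "C")
}

# Full 14-bp site: left half on sense, right half written as the reverse
# complement of its half-site reading (so a site with dLeft == dRight is a
# perfect palindrome up to backbone noise).
.makeSite <- function(dLeft, dRight, identity = 0.9) {
  paste0(.makeHalfSite(dLeft, identity),
         revComp(.makeHalfSite(dRight, identity)))
}

# Draw n (left, right) semisequence pairs for one class under its
# degeneracy spec. Returns a 2-column character matrix.
.drawQuartets <- function(entries, spec, n) {
  semis <- entries$semiseq
  w <- entries$weight
  type <- spec$type
  if (type == "none") {
    cbind(rep(semis[1], n), rep(semis[1], n))
  } else if (type == "sym_intrinsic") {
    # independent half sites: palindromes and both mixtures all reachable
    cbind(sample(semis, n, replace = TRUE, prob = w),
          sample(semis, n, replace = TRUE, prob = w))
  } else if (type == "asym_intrinsic") {
    dom <- spec$dominant; minor <- spec$minor; p <- spec$dominant_prob
    # dominant palindrome with probability p; residual mass split uniformly
    # over the two ordered mixtures and the minor palindrome
    cfg <- sample(4L, n, replace = TRUE,
                  prob = c(p, (1 - p) / 3, (1 - p) / 3, (1 - p) / 3))
    cbind(c(dom, dom, minor, minor)[cfg],
          c(dom, minor, dom, minor)[cfg])
  } else if (type == "extrinsic") {
    # resolved per TF, not per site; handled by the caller
    stop("extrinsic specs are resolved per TF in generateRegions")
  } else stop("unknown degeneracy type: ", type)
}

#' Generate a synthetic domain family with a planted code
#'
#' Builds a gapless 71-column amino-acid alignment for
#' \code{nClasses * tfsPerClass} regulators. Columns 15 and 16 carry each
#' class's recognition pair, columns 17-20 are fixed to T,V,S,R (the
#' dominant recognition-helix subgroup) and the structural hinge-helix
#' columns 51 and 54 are fixed to A and L. Every other column draws from a
#' random per-column consensus with per-column conservation noise.
#'
#' @param nClasses number of recognition classes; must equal the number of
#'   distinct classes in \code{code}.
#' @param tfsPerClass regulators per class.
#' @param code a \code{\linkS4class{PlantedCode}}; duplicate aa pairs across
#'   classes are impossible by construction and rejected.
#' @param seed integer seed (mandatory; same seed gives identical output).
#' @param width alignment width (default 71 columns).
#' @param conservationRange range of per-column background conservation.
#' @return list with \code{alignment} (a
#'   \code{\linkS4class{DomainAlignment}}) and \code{classMap}
#'   (data.frame \code{tf_id}, \code{aa_pair}).
#' @examples
#' fam <- generateFamily(2, 3, plantedCode(c(KA = "TG", YQ = "TA")), seed = 1)
#' fam$classMap
#' @export
generateFamily <- function(nClasses, tfsPerClass, code, seed,
                           width = 71L, conservationRange = c(0.5, 0.9)) {
  stopifnot(nClasses >= 1L, tfsPerClass >= 1L,
            methods::is(code, "PlantedCode"))
  classes <- codeClasses(code)
  if (length(classes) != nClasses)
    stop("code covers ", length(classes), " distinct aa pairs, expected ",
         nClasses)
  set.seed(.checkSeed(seed))
  nSeq <- nClasses * tfsPerClass
  # per-column background consensus and conservation level
  consensus <- sample(AA_ALPHABET20, width, replace = TRUE)
  conservation <- runif(width, conservationRange[1], conservationRange[2])
  aln <- matrix("", nrow = nSeq, ncol = width)
  for (j in seq_len(width)) {
    keep <- runif(nSeq) < conservation[j]
    aln[, j] <- ifelse(keep, consensus[j],
                       sample(AA_ALPHABET20, nSeq, replace = TRUE))
  }
  tfIds <- character(nSeq)
  aaPairs <- character(nSeq)
  for (ci in seq_along(classes)) {
    rows <- (ci - 1L) * tfsPerClass + seq_len(tfsPerClass)
    pair <- strsplit(classes[ci], "", fixed = TRUE)[[1]]
    aln[rows, 15] <- pair[1]
    aln[rows, 16] <- pair[2]
    aln[rows, 17:20] <- matrix(rep(c("T", "V", "S", "R"),
                                   each = tfsPerClass), ncol = 4)
    tfIds[rows] <- sprintf("tf_%s_%02d", classes[ci], seq_len(tfsPerClass))
    aaPairs[rows] <- classes[ci]
  }
  aln[, 51] <- "A"
  aln[, 54] <- "L"
  seqs <- stats::setNames(apply(aln, 1, paste, collapse = ""), tfIds)
  list(alignment = DomainAlignment(seqs),
       classMap = data.frame(tf_id = tfIds, aa_pair = aaPairs,
                             stringsAsFactors = FALSE))
}

#' Generate per-regulator intergenic regions with planted sites
#'
#' For every regulator, draws one strict upstream non-coding region
#' (\code{regionLen} bp, at most 200) and an extended 250-bp version that
#' appends the first 50 coding positions and pads upstream context, so the
#' strict region maps into the extended one at offset
#' \code{200 - regionLen}. With probability \code{siteRate} a 14-bp site is
#' planted at a uniform offset: its NT-6 is G, the central CG is present,
#' and the (NT-5, NT-4) semisequences are drawn from the class's code entry
#' respecting its degeneracy spec. All planted sites are recorded in the
#' returned truth table (sense-strand, 0-based half-open starts).
#'
#' @param classMap data.frame \code{tf_id}, \code{aa_pair}.
#' @param code a \code{\linkS4class{PlantedCode}} covering every class in
#'   \code{classMap}.
#' @param siteRate probability that a region receives a planted site
#'   (in (0, 1]; 0 gives pure-background regions).
#' @param regionLen strict region length, 50..200 bp.
#' @param background length-4 base probabilities (A,C,G,T).
#' @param seed integer seed.
#' @param identity per-position backbone match probability outside the
#'   conserved/variable slots.
#' @param minusStrandRate fraction of planted sites written on the minus
#'   strand (default 0: palindromic sites are strand-symmetric; nonzero
#'   values exercise scanner strand handling).
#' @param downstream also emit one downstream region per regulator
#'   (region id \code{<tf>_down}, same length and planting model as the
#'   upstream one; local regulation covers the adjacent downstream
#'   operon as well as autoregulation).
#' @return list with \code{strict} and \code{extended} (named character
#'   vectors of regions, region id \code{<tf>_up}), \code{truth}
#'   (data.frame \code{tf_id}, \code{region_id}, \code{start},
#'   \code{start_extended}, \code{strand}, \code{site_seq}, \code{d_left},
#'   \code{d_right}) and \code{classMap}.
#' @export
generateRegions <- function(classMap, code, siteRate = 0.8, regionLen = 150L,
                            background = rep(0.25, 4), seed,
                            identity = 0.9, minusStrandRate = 0,
                            downstream = FALSE) {
  regionLen <- as.integer(regionLen)
  stopifnot(regionLen >= 50L, siteRate >= 0, siteRate <= 1)
  if (regionLen > 200L) stop("strict regions are truncated at 200 bp")
  if (regionLen < 14L) stop("site longer than region")
  stopifnot(abs(sum(background) - 1) < 1e-8)
  set.seed(.checkSeed(seed))
  w <- 14L
  extPad <- 200L - regionLen   # upstream context added in the extended view
  codingLen <- 50L
  strict <- character(0); extended <- character(0)
  truth <- list()
  # per-TF semiseq assignment for extrinsic classes (round-robin over entries)
  extAssign <- list()
  for (cls in codeClasses(code)) {
    if (codeDegeneracy(code)[[cls]]$type == "extrinsic") {
      members <- classMap$tf_id[classMap$aa_pair == cls]
      semis <- codeEntries(code)$semiseq[codeEntries(code)$aa_pair == cls]
      extAssign[[cls]] <- stats::setNames(
        semis[(seq_along(members) - 1L) %% length(semis) + 1L], members)
    }
  }
  rndSeq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE,
                                     prob = background), collapse = "")
  kinds <- if (downstream) c("_up", "_down") else "_up"
  for (i in seq_len(nrow(classMap))) for (kind in kinds) {
    tf <- classMap$tf_id[i]
    cls <- classMap$aa_pair[i]
    if (!cls %in% codeClasses(code))
      stop("classMap references class absent from code: ", cls)
    rid <- paste0(tf, kind)
    seqStrict <- rndSeq(regionLen)
    if (runif(1) < siteRate) {
      spec <- codeDegeneracy(code)[[cls]]
      ent <- codeEntries(code)[codeEntries(code)$aa_pair == cls, , drop = FALSE]
      q <- if (spec$type == "extrinsic") {
        s <- extAssign[[cls]][[tf]]
        matrix(c(s, s), nrow = 1)
      } else .drawQuartets(ent, spec, 1L)
      site <- .makeSite(q[1, 1], q[1, 2], identity)
      strand <- if (runif(1) < minusStrandRate) "-" else "+"
      planted <- if (strand == "-") revComp(site) else site
      start <- sample.int(regionLen - w + 1L, 1L) - 1L
      substr(seqStrict, start + 1L, start + w) <- planted
      truth[[length(truth) + 1L]] <- data.frame(
        tf_id = tf, region_id = rid, start = start,
        start_extended = start + extPad, strand = strand,
        site_seq = site, d_left = q[1, 1], d_right = q[1, 2],
        stringsAsFactors = FALSE)
    }
    strict[rid] <- seqStrict
    extended[rid] <- paste0(rndSeq(extPad), seqStrict, rndSeq(codingLen))
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(tf_id = character(0), region_id = character(0),
               start = integer(0), start_extended = integer(0),
               strand = character(0), site_seq = character(0),
               d_left = character(0), d_right = character(0),
               stringsAsFactors = FALSE)
  list(strict = strict, extended = extended, truth = truth,
       classMap = classMap)
}

#' Generate binding-site sets under the three degeneracy scenarios
#'
#' Draws \code{nSites} full 14-bp sites whose half-site semisequences
#' follow one of the benchmark scenarios for a class binding two
#' semisequences \code{a} and \code{b}:
#' \describe{
#'   \item{both_high_affinity}{half sites independent and equiprobable, so
#'     palindromes P1, P2 and both mixtures are all populated (mixture
#'     fraction 1/2 at equal weights).}
#'   \item{preferential}{half sites independent with probability
#'     \code{dominantProb} for the dominant half site: one palindrome
#'     dominates, mixtures are rare, the minor palindrome rarer.}
#'   \item{exclusive}{only the two palindromes occur (each pseudo-regulator
#'     is specific to a single half-site type), zero mixtures.}
#' }
#' Mixture configurations are additionally weighted by
#' \code{mixEnergyRatio} (1 = mixtures carry the same binding energy as
#' the palindromes predict under independent pairing).
#'
#' @param scenario one of \code{"both_high_affinity"}, \code{"preferential"},
#'   \code{"exclusive"}.
#' @param nSites number of sites (>= 1).
#' @param semiseqs character vector of two distinct semisequences.
#' @param mixEnergyRatio weight multiplier on mixture configurations.
#' @param dominantProb per-half-site preference for \code{semiseqs[1]} under
#'   the preferential scenario; 1 removes mixtures entirely.
#' @param seed integer seed.
#' @param identity backbone match probability (see
#'   \code{\link{generateRegions}}).
#' @return character vector of site sequences with attribute
#'   \code{"config"}: factor over P1, P2, M1, M2.
#' @export
generateDegeneracySites <- function(scenario = c("both_high_affinity",
                                                 "preferential", "exclusive"),
                                    nSites, semiseqs, mixEnergyRatio = 1,
                                    dominantProb = 0.85, seed,
                                    identity = 0.9) {
  scenario <- match.arg(scenario)
  stopifnot(length(semiseqs) == 2L, semiseqs[1] != semiseqs[2], nSites >= 1L)
  set.seed(.checkSeed(seed))
  a <- semiseqs[1]; b <- semiseqs[2]
  q <- switch(scenario,
              both_high_affinity = 0.5,
              preferential = dominantProb,
              exclusive = NA_real_)
  probs <- if (scenario == "exclusive") {
    c(P1 = 0.5, P2 = 0.5, M1 = 0, M2 = 0)
  } else {
    p <- c(P1 = q^2, P2 = (1 - q)^2,
           M1 = q * (1 - q) * mixEnergyRatio,
           M2 = (1 - q) * q * mixEnergyRatio)
    p / sum(p)
  }
  cfg <- sample(names(probs), nSites, replace = TRUE, prob = probs)
  halves <- list(P1 = c(a, a), P2 = c(b, b), M1 = c(a, b), M2 = c(b, a))
  sites <- vapply(cfg, function(cf) {
    h <- halves[[cf]]
    .makeSite(h[1], h[2], identity)
  }, character(1), USE.NAMES = FALSE)
  attr(sites, "config") <- factor(cfg, levels = names(probs))
  sites
}

#' Mononucleotide shuffle of a sequence
#'
#' Returns a random permutation of the input letters; base composition is
#' preserved exactly.
#'
#' @param seq non-empty sequence over A,C,G,T,N (character scalar).
#' @param seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used (callers that shuffle repeatedly seed once upstream).
#' @return shuffled sequence (character scalar).
#' @examples
#' shuffleRegion("ACGTACGT", seed = 1)
#' @export
shuffleRegion <- function(seq, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  if (grepl("[^ACGTN]", toupper(seq))) stop("sequence must be over {A,C,G,T,N}")
  if (!is.null(seed)) set.seed(.checkSeed(seed))
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(letters[sample.int(length(letters))], collapse = "")
}
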