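#' Planted recognition code for synthetic families
#'
#' Ground-truth association between recognition-residue pairs (the residues
#' at alignment columns 15 and 16) and operator half-site dinucleotides
#' (positions NT-5 and NT-4 of the left half site). Each entry assigns one
#' semisequence and a weight to a class; classes with several entries are
#' degenerate and the per-class \code{degeneracy} spec states how sites are
#' drawn (see \code{\link{generateRegions}}).
#'
#' @slot entries data.frame with columns \code{aa_pair} (two amino-acid
#'   letters), \code{semiseq} (two DNA letters, the left-half (NT-5, NT-4))
#'   and \code{weight} (per-class weights summing to 1).
#' @slot degeneracy named list (one element per \code{aa_pair}); each element
#'   is a list with \code{type} in \code{"none"}, \code{"sym_intrinsic"},
#'   \code{"asym_intrinsic"} (fields \code{dominant}, \code{minor},
#'   \code{dominant_prob} in (0.5, 1]) or \code{"extrinsic"}.
#' @seealso \code{\link{plantedCode}}, \code{\link{generateFamily}}
#' @exportClass PlantedCode
setClass("PlantedCode",
         slots = c(entries = "data.frame", degeneracy = "list"))

setValidity("PlantedCode", function(object) {
  e <- object@entries
  msgs <- character(0)
  need <- c("aa_pair", "semiseq", "weight")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(grepl("^[A-Z]{2}$", e$aa_pair)))
    msgs <- c(msgs, "aa_pair must be two uppercase amino-acid letters")
  if (!all(grepl("^[ACGT]{2}$", e$semiseq)))
    msgs <- c(msgs, "semiseq must be two letters over {A,C,G,T}")
  w <- tapply(e$weight, e$aa_pair, sum)
  if (any(abs(w - 1) > 1e-8))
    msgs <- c(msgs, "weights must sum to 1 within each aa_pair")
  if (any(e$weight < 0))
    msgs <- c(msgs, "weights must be non-negative")
  for (cls in names(object@degeneracy)) {
    d <- object@degeneracy[[cls]]
    if (!cls %in% e$aa_pair) {
      msgs <- c(msgs, sprintf("degeneracy spec for unknown class '%s'", cls))
      next
    }
    if (!d$type %in% c("none", "sym_intrinsic", "asym_intrinsic", "extrinsic"))
      msgs <- c(msgs, sprintf("unknown degeneracy type '%s'", d$type))
    if (identical(d$type, "asym_intrinsic")) {
      if (is.null(d$dominant) || is.null(d$minor) || is.null(d$dominant_prob))
        msgs <- c(msgs, "asym_intrinsic needs dominant, minor, dominant_prob")
      else if (d$dominant_prob <= 0.5 || d$dominant_prob > 1)
        msgs <- c(msgs, "dominant_prob must be in (0.5, 1]")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a planted recognition code
#'
#' @param entries either a named character vector mapping class
#'   \code{aa_pair} to a single semisequence (weights of 1), or a data.frame
#'   with columns \code{aa_pair}, \code{semiseq}, \code{weight}.
#' @param degeneracy named list of per-class degeneracy specs; classes left
#'   unspecified default to \code{"none"} (single entry) or
#'   \code{"sym_intrinsic"} (several entries).
#' @return a \code{\linkS4class{PlantedCode}} object.
#' @examples
#' plantedCode(c(KA = "TG", YQ = "TA"))
#' @export
plantedCode <- function(entries, degeneracy = list()) {
  if (is.character(entries)) {
    stopifnot(!is.null(names(entries)))
    entries <- data.frame(aa_pair = names(entries),
                          semiseq = unname(entries),
                          weight = 1,
                          stringsAsFactors = FALSE)
  }
  entries$aa_pair <- as.character(entries$aa_pair)
  entries$semiseq <- as.character(entries$semiseq)
  for (cls in unique(entries$aa_pair)) {
    if (is.null(degeneracy[[cls]])) {
      n <- sum(entries$aa_pair == cls)
      degeneracy[[cls]] <- list(type = if (n == 1L) "none" else "sym_intrinsic")
    }
  }
  methods::new("PlantedCode", entries = entries, degeneracy = degeneracy)
}

#' @describeIn plantedCode distinct classes (aa pairs) of a code, sorted.
#' @param code a \code{PlantedCode}.
#' @export
codeClasses <- function(code) sort(unique(code@entries$aa_pair))

#' @describeIn plantedCode the entries table of a code.
#' @export
codeEntries <- function(code) code@entries

#' @describeIn plantedCode the per-class degeneracy specification list.
#' @export
codeDegeneracy <- function(code) code@degeneracy

setMethod("show", "PlantedCode", function(object) {
  cat("PlantedCode with", length(codeClasses(object)), "recognition classes,",
      nrow(object@entries), "entries\n")
  print(object@entries, row.names = FALSE)
})

#' Aligned DNA-binding-domain set in a fixed column frame
#'
#' A rectangular amino-acid alignment whose column numbering is the fixed
#' coordinate frame used for all residue positions in the package (the
#' recognition helix spans columns 15-22; hinge-helix residues sit at
#' columns 51 and 54). Rows are regulators, identified by name.
#'
#' @slot seqs an \code{\link[Biostrings]{AAStringSet}} of equal-width
#'   aligned sequences (gaps as \code{-}), uniquely named.
#' @seealso \code{\link{recognitionResidues}}, \code{\link{partitionClasses}}
#' @exportClass DomainAlignment
setClass("DomainAlignment", slots = c(seqs = "AAStringSet"))

setValidity("DomainAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) == 0L) return("alignment must contain at least one sequence")
  if (length(unique(w)) != 1L)
    return("ragged alignment: all sequences must have equal width")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    return("sequences must carry unique non-empty names")
  TRUE
})

#' Construct a DomainAlignment
#'
#' @param seqs named character vector or \code{AAStringSet} of equal-width
#'   aligned amino-acid sequences.
#' @return a \code{\linkS4class{DomainAlignment}}.
#' @export
DomainAlignment <- function(seqs) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  methods::new("DomainAlignment", seqs = seqs)
}

#' @describeIn DomainAlignment aligned sequences as a named character vector.
#' @param x a \code{DomainAlignment}.
#' @export
alignedSeqs <- function(x) {
  stopifnot(methods::is(x, "DomainAlignment"))
  stats::setNames(as.character(x@seqs), names(x@seqs))
}

#' @describeIn DomainAlignment alignment width (number of columns).
#' @export
alignmentWidth <- function(x) {
  stopifnot(methods::is(x, "DomainAlignment"))
  unique(Biostrings::width(x@seqs))
}

setMethod("show", "DomainAlignment", function(object) {
  cat("DomainAlignment:", length(object@seqs), "sequences x",
      alignmentWidth(object), "columns\n")
})

setMethod("length", "DomainAlignment", function(x) length(x@seqs))

#' Palindrome-capable position weight matrix
#'
#' Count-based PWM over A,C,G,T with a constant pseudocount: cell
#' frequencies are \code{(count + B/4) / (N + B)} where \code{N} is the
#' (possibly fractional, after palindromic symmetrization) number of sites
#' per column and \code{B} the pseudocount constant. Log-odds are taken
#' base 2 against the background. When \code{palindromic} is \code{TRUE}
#' the count matrix equals its own reverse complement.
#'
#' @slot counts 4 x width numeric matrix, rows A,C,G,T.
#' @slot pseudocount constant B (total pseudo-observations per column).
#' @slot background length-4 probability vector over A,C,G,T.
#' @slot palindromic logical flag.
#' @seealso \code{\link{buildPWM}}, \code{\link{scanPWM}}
#' @exportClass RecognitionPWM
setClass("RecognitionPWM",
         slots = c(counts = "matrix", pseudocount = "numeric",
                   background = "numeric", palindromic = "logical"))

setValidity("RecognitionPWM", function(object) {
  m <- object@counts
  msgs <- character(0)
  if (nrow(m) != 4L) msgs <- c(msgs, "counts must have 4 rows (A,C,G,T)")
  if (any(m < 0)) msgs <- c(msgs, "counts must be non-negative")
  cs <- colSums(m)
  if (ncol(m) > 0 && diff(range(cs)) > 1e-6)
    msgs <- c(msgs, "column sums of counts must be equal")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-8)
    msgs <- c(msgs, "background must be 4 probabilities summing to 1")
  if (object@pseudocount < 0) msgs <- c(msgs, "pseudocount must be >= 0")
  if (isTRUE(object@palindromic) &&
      max(abs(m - .revCompMatrix(m))) > 1e-9)
    msgs <- c(msgs, "palindromic PWM must equal its reverse complement")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn RecognitionPWM raw (possibly symmetrized) count matrix.
#' @param pwm a \code{RecognitionPWM}.
#' @export
pwmCounts <- function(pwm) pwm@counts

#' @describeIn RecognitionPWM motif width in base pairs.
#' @export
pwmWidth <- function(pwm) ncol(pwm@counts)

#' @describeIn RecognitionPWM whether the matrix is palindrome-constrained.
#' @export
isPalindromic <- function(pwm) pwm@palindromic

#' @describeIn RecognitionPWM pseudocounted frequency matrix
#'   \code{(count + B/4)/(N + B)}.
#' @export
pwmFrequencies <- function(pwm) {
  m <- pwm@counts
  n <- if (ncol(m)) colSums(m)[1] else 0
  (m + pwm@pseudocount / 4) / (n + pwm@pseudocount)
}

#' @describeIn RecognitionPWM base-2 log-odds matrix versus background.
#' @export
pwmLogOdds <- function(pwm) {
  log2(pwmFrequencies(pwm) / pwm@background)
}

setMethod("show", "RecognitionPWM", function(object) {
  cat(sprintf("RecognitionPWM: width %d, %s, N = %.4g sites, B = %.3g\n",
              pwmWidth(object),
              if (object@palindromic) "palindromic" else "unconstrained",
              if (pwmWidth(object)) colSums(object@counts)[1] else 0,
              object@pseudocount))
  cons <- apply(pwmFrequencies(object), 2, function(p) DNA_BASES[which.max(p)])
  cat("consensus:", paste(cons, collapse = ""), "\n")
})
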