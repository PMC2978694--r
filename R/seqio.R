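# Readers and writers for every on-disk format the pipeline touches:
# FASTA (plain and aligned), TSV site tables, BED6 export, and a minimal
# text motif format. Coordinates are 0-based half-open everywhere.

SITE_COLUMNS <- c("tf_id", "region_id", "start", "end", "strand",
                  "sequence", "score", "zscore", "confidence")

#' Empty site table
#'
#' Zero-row data.frame with the canonical site-table columns: identifiers,
#' 0-based half-open coordinates, strand, matched sequence (reverse
#' complemented for minus-strand sites), log-odds score, Z-score and
#' sampler confidence.
#'
#' @return data.frame with 0 rows and the canonical columns.
#' @export
emptySiteTable <- function() {
  data.frame(tf_id = character(0), region_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             sequence = character(0), score = numeric(0),
             zscore = numeric(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

# Validate the site-table contract; returns the table invisibly.
.validateSiteTable <- function(sites, regions = NULL) {
  if (!all(SITE_COLUMNS %in% names(sites)))
    stop("site table must have columns: ", paste(SITE_COLUMNS, collapse = ", "))
  if (nrow(sites) == 0L) return(invisible(sites))
  if (any(sites$start >= sites$end))
    stop("site table: start must be < end (0-based half-open)")
  if (any(sites$end - sites$start != nchar(sites$sequence)))
    stop("site table: end - start must equal sequence length")
  if (!all(sites$strand %in% c("+", "-")))
    stop("site table: strand must be '+' or '-'")
  if (!is.null(regions)) {
    regions <- .asSeqVector(regions)
    for (i in seq_len(nrow(sites))) {
      sl <- .slice(regions[[sites$region_id[i]]], sites$start[i], sites$end[i])
      if (sites$strand[i] == "-") sl <- revComp(sl)
      if (!identical(sl, sites$sequence[i]))
        stop("site table row ", i, ": sequence does not match region slice")
    }
  }
  invisible(sites)
}

#' Read a FASTA file
#'
#' Thin wrapper around Biostrings that normalizes lowercase letters to
#' uppercase (with a message) and optionally enforces the aligned-FASTA
#' contract of equal sequence widths.
#'
#' @param path file path.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @param aligned require equal widths (error on ragged input).
#' @return a \code{DNAStringSet} or \code{AAStringSet}.
#' @export
readFasta <- function(path, type = c("DNA", "AA"), aligned = FALSE) {
  type <- match.arg(type)
  raw <- Biostrings::readBStringSet(path)
  seqs <- as.character(raw)
  if (any(seqs != toupper(seqs))) {
    message("readFasta: lowercase letters normalized to uppercase")
    seqs <- toupper(seqs)
  }
  if (aligned && length(seqs) > 1L && length(unique(nchar(seqs))) != 1L)
    stop("alignment-length error: ragged aligned FASTA in ", path)
  names(seqs) <- names(raw)
  if (type == "DNA") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param x named character vector or \code{XStringSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a PWM in a minimal text motif format
#'
#' One motif per file: a \code{MOTIF <name>} line, a header giving alphabet
#' size, width and site count, then one row of four frequencies (A C G T)
#' per motif position. Frequencies round-trip within 1e-9 per cell.
#'
#' @param pwm a \code{\linkS4class{RecognitionPWM}}.
#' @param path file path.
#' @param name motif name written to the file.
#' @return \code{path} (writer) or a \code{RecognitionPWM} (reader).
#' @export
writeMotif <- function(pwm, path, name = "motif") {
  stopifnot(methods::is(pwm, "RecognitionPWM"))
  if (any(pwm@counts < 0)) stop("negative counts in PWM")
  fr <- pwmFrequencies(pwm)
  n <- colSums(pwm@counts)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %.9g pseudocount= %.9g palindromic= %d",
                       ncol(fr), n, pwm@pseudocount, as.integer(pwm@palindromic))),
             con)
  for (j in seq_len(ncol(fr)))
    writeLines(paste(sprintf("%.12f", fr[, j]), collapse = " "), con)
  invisible(path)
}

#' @rdname writeMotif
#' @export
readMotif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !startsWith(lines[1], "MOTIF"))
    stop("motif format error: missing MOTIF header in ", path)
  hdr <- lines[2]
  getNum <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "= ([0-9eE.+-]+)"), hdr))[[1]]
    if (length(m) < 2L) stop("motif format error: missing ", key, " in header")
    as.numeric(m[2])
  }
  w <- as.integer(getNum("w"))
  n <- getNum("nsites")
  b <- getNum("pseudocount")
  pal <- getNum("palindromic") == 1
  rows <- lines[-(1:2)]
  if (length(rows) != w)
    stop("motif format error: expected ", w, " matrix rows, found ", length(rows))
  fr <- vapply(rows, function(l) {
    v <- as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
    if (length(v) != 4L) stop("motif format error: row does not have 4 columns")
    v
  }, numeric(4))
  rownames(fr) <- DNA_BASES
  # invert the pseudocount smoothing to recover counts
  counts <- fr * (n + b) - b / 4
  counts[abs(counts) < 1e-9] <- 0
  if (any(counts < 0)) stop("negative counts reconstructed from ", path)
  methods::new("RecognitionPWM", counts = counts, pseudocount = b,
               background = rep(0.25, 4), palindromic = pal)
}

#' Write / read a site table as TSV
#'
#' Tab-separated with header; numeric fields are printed with full
#' precision so that tables round-trip identically. \code{readSites}
#' rejects rows with \code{start >= end}.
#'
#' @param sites a site-table data.frame (see \code{\link{emptySiteTable}}).
#' @param path file path.
#' @return \code{path} (writer) or the site table (reader).
#' @export
writeSites <- function(sites, path) {
  .validateSiteTable(sites)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- paste(SITE_COLUMNS, collapse = "\t")
  if (nrow(sites)) {
    body <- paste(sites$tf_id, sites$region_id, sites$start, sites$end,
                  sites$strand, sites$sequence, fmt(sites$score),
                  fmt(sites$zscore), fmt(sites$confidence), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSites
#' @export
readSites <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c(tf_id = "character", region_id = "character",
                                  start = "integer", end = "integer",
                                  strand = "character", sequence = "character",
                                  score = "numeric", zscore = "numeric",
                                  confidence = "numeric"))
  if (nrow(df) && any(df$start >= df$end))
    stop("invalid site table: start >= end in ", path)
  .validateSiteTable(df)
  df
}

#' Export a site table as BED6
#'
#' Chromosome is the region id; the BED score column is the confidence
#' scaled to 0-1000 when available, otherwise the log-odds score clamped
#' into 0-1000. Coordinates stay 0-based half-open, as BED requires.
#'
#' @param sites a site-table data.frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
sitesToBed <- function(sites, path) {
  .validateSiteTable(sites)
  score <- ifelse(!is.na(sites$confidence),
                  round(1000 * pmin(pmax(sites$confidence, 0), 1)),
                  round(pmin(pmax(sites$score, 0), 1000)))
  lines <- if (nrow(sites))
    paste(sites$region_id, sites$start, sites$end, sites$tf_id,
          score, sites$strand, sep = "\t")
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a planted-site truth table
#'
#' TSV with columns \code{tf_id}, \code{region_id}, \code{start} (0-based
#' half-open, strict-region coordinates), \code{start_extended} (the same
#' site in extended-region coordinates), \code{strand} and \code{site_seq}.
#'
#' @param truth data.frame as produced by \code{\link{generateRegions}}.
#' @param path file path.
#' @return \code{path} (writer) or the truth table (reader).
#' @export
writeTruth <- function(truth, path) {
  cols <- c("tf_id", "region_id", "start", "start_extended", "strand",
            "site_seq")
  stopifnot(all(cols %in% names(truth)))
  write.table(truth[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  read.delim(path, sep = "\t", header = TRUE,
             colClasses = c(tf_id = "character", region_id = "character",
                            start = "integer", start_extended = "integer",
                            strand = "character", site_seq = "character"))
}
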