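# Shared fixture builders. Everything is generated in code; no data files.

# Deterministic 14-bp site on the canonical backbone with given left/right
# semisequences (NT-2 fixed to T): the noise-free analog of the generator's
# planted sites.
consensusSite <- function(dLeft, dRight = dLeft, nt2 = "T") {
  half <- function(d) paste0("TG", d, "A", nt2, "C")
  paste0(half(dLeft), revComp(half(dRight)))
}

# Small planted code shared across tests.
testCode <- function() plantedCode(c(KA = "TG", YQ = "TA"))

# Uniform random DNA of length n using the current RNG stream.
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force window log-odds scoring oracle, independent of scanPWM's
# vectorized path: per-window explicit summation.
bruteForceScores <- function(pwm, region) {
  lo <- pwmLogOdds(pwm)
  w <- pwmWidth(pwm)
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  vapply(seq_len(nchar(region) - w + 1L), function(j) {
    s <- 0
    for (k in seq_len(w)) {
      b <- match(chars[j + k - 1L], c("A", "C", "G", "T"))
      s <- s + lo[b, k]
    }
    s
  }, numeric(1))
}

# Exhaustive quartet-count oracle: tabulate unordered half-site pairs by
# direct string handling (no shared code with buildCombinationMatrix's
# factor/table path beyond the quartet reader itself being re-derived).
oracleQuartetCounts <- function(sites) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  keys <- vapply(sites, function(s) {
    l <- substr(s, 3, 4)
    r <- rc(substr(s, 11, 12))
    paste(sort(c(l, r)), collapse = "|")
  }, character(1), USE.NAMES = FALSE)
  table(keys)
}

# Direct-summation mutual information oracle over two symbol vectors.
oracleMI <- function(x, y) {
  n <- length(x)
  tot <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0)
      tot <- tot + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  tot
}
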