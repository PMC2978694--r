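test_that("PWM construction applies the constant pseudocount per cell", {
  # one of each base per column, B = 0: uniform frequencies, zero log-odds
  sites4 <- c("AAAA", "CCCC", "GGGG", "TTTT")
  pwm <- buildPWM(sites4, pseudocount = 0)
  expect_equal(unname(pwmFrequencies(pwm)), matrix(0.25, 4, 4))
  expect_equal(unname(pwmLogOdds(pwm)), matrix(0, 4, 4))

  # single site, B = 1: matching cells (1 + 0.25) / (1 + 1) = 0.625
  single <- buildPWM(consensusSite("TG"), pseudocount = 1)
  fr <- pwmFrequencies(single)
  chars <- strsplit(consensusSite("TG"), "")[[1]]
  for (j in 1:14) {
    expect_equal(unname(fr[chars[j], j]), 0.625)
    expect_equal(sum(fr[, j]), 1, tolerance = 1e-9)
  }

  expect_error(buildPWM(character(0)), "at least one")
  expect_error(buildPWM(c("ACGT", "ACGTA")), "width mismatch")
})

test_that("palindromic PWMs equal their reverse complement after every build", {
  set.seed(4)
  for (i in 1:5) {
    sites <- replicate(6, randomDNA(14))
    pwm <- buildPWM(sites, pseudocount = 1, palindromic = TRUE)
    m <- pwmCounts(pwm)
    expect_equal(unname(m), unname(m[4:1, 14:1]))
  }
})

test_that("scanning equals brute-force window summation and counts windows", {
  set.seed(21)
  pwm <- buildPWM(replicate(5, randomDNA(14)), pseudocount = 1)
  for (i in 1:5) {
    region <- c(r = randomDNA(60))
    got <- scanPWM(pwm, region, minScore = -Inf)
    plus <- got[got$strand == "+", ]
    expect_identical(nrow(plus), 60L - 14L + 1L)
    oracle <- bruteForceScores(pwm, region[[1]])
    expect_lt(max(abs(plus$score[order(plus$start)] - oracle)), 1e-9)
  }

  # consensus embedded in weak background is the unique top candidate
  embedded <- c(r = paste0(strrep("A", 20), consensusSite("TG"),
                           strrep("A", 20)))
  palPwm <- buildPWM(rep(consensusSite("TG"), 4), pseudocount = 1,
                     palindromic = TRUE)
  consScore <- sum(pwmLogOdds(palPwm)[cbind(
    match(strsplit(consensusSite("TG"), "")[[1]], c("A", "C", "G", "T")),
    1:14)])
  hit <- scanPWM(palPwm, embedded, minScore = consScore)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 20L)
  expect_identical(hit$strand, "+")  # palindromic hits collapse to sense
})

test_that("null score distributions are deterministic and well calibrated", {
  flat <- buildPWM(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  regions <- c(r1 = strrep("ACGT", 30), r2 = strrep("GTCA", 30))
  nd <- nullScores(flat, regions, nNull = 1000, seed = 3)
  expect_identical(nd$n, 1000L)
  expect_true(all(nd$scores == 0))  # zero log-odds everywhere

  set.seed(50)
  pwm <- buildPWM(replicate(6, randomDNA(14)), pseudocount = 1)
  a <- nullScores(pwm, regions, nNull = 2000, seed = 7)
  b <- nullScores(pwm, regions, nNull = 2000, seed = 7)
  expect_identical(a$scores, b$scores)

  # empirical p-values of null scores against their own null are
  # super-uniform: the one-sided KS test against the anti-conservative
  # direction must not reject (score ties from the discrete log-odds
  # lattice push p-values up, which is the safe direction)
  p <- empiricalP(a$scores, a)
  ks <- suppressWarnings(stats::ks.test(p, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(p > 0 & p <= 1))
})

test_that("a planted consensus is extreme against a background null", {
  set.seed(60)
  regions <- stats::setNames(replicate(10, randomDNA(200)),
                             sprintf("r%02d", 1:10))
  pwm <- buildPWM(rep(consensusSite("TG"), 5), pseudocount = 1,
                  palindromic = TRUE)
  nd <- nullScores(pwm, regions, nNull = 1e5, seed = 61)
  consScore <- sum(pwmLogOdds(pwm)[cbind(
    match(strsplit(consensusSite("TG"), "")[[1]], c("A", "C", "G", "T")),
    1:14)])
  expect_lt(empiricalP(consScore, nd), 0.001)
})

test_that("refinement recovers planted sites and respects fixed points", {
  code <- plantedCode(c(KA = "TG"))
  sens <- numeric(0); prec <- numeric(0)
  for (sd in 1:10) {
    classMap <- data.frame(tf_id = sprintf("tf_KA_%02d", 1:20),
                           aa_pair = "KA")
    reg <- generateRegions(classMap, code, siteRate = 0.8, regionLen = 150,
                           seed = sd)
    seeds <- gibbsSearch(reg$strict, gibbsConfig(seed = sd + 300))
    ref <- refineSites(seeds, reg$extended, nNull = 2e4, seed = sd + 400)
    m <- matchPlantedSites(ref$sites, reg$truth, "start_extended",
                           startTol = 14L)  # overlap-level match
    sens <- c(sens, m["n_found"] >= 0.9 * m["n_planted"] &&
                m["n_found"] <= 1.1 * m["n_planted"])
    prec <- c(prec, m["precision"])
  }
  expect_gte(mean(sens), 0.9)     # recovered count within 10% of planted
  expect_gte(mean(prec >= 0.9), 0.9)

  # alpha = 1: every candidate at or above the seed minimum survives
  classMap <- data.frame(tf_id = sprintf("tf_KA_%02d", 1:8), aa_pair = "KA")
  reg <- generateRegions(classMap, code, siteRate = 1, regionLen = 100,
                         seed = 77)
  seeds <- gibbsSearch(reg$strict, gibbsConfig(seed = 78))
  loose <- refineSites(seeds, reg$extended, nNull = 1000, alpha = 1,
                       seed = 79)
  expect_gte(nrow(loose$sites), nrow(seeds))

  # determinism of the whole refinement
  again <- refineSites(seeds, reg$extended, nNull = 1000, alpha = 1,
                       seed = 79)
  expect_identical(loose$sites, again$sites)
})

test_that("an already-converged seed set is a one-iteration fixed point", {
  code <- plantedCode(c(KA = "TG"))
  classMap <- data.frame(tf_id = sprintf("tf_KA_%02d", 1:10), aa_pair = "KA")
  reg <- generateRegions(classMap, code, siteRate = 1, regionLen = 120,
                         seed = 31)
  seeds <- gibbsSearch(reg$strict, gibbsConfig(seed = 32))
  first <- refineSites(seeds, reg$extended, nNull = 5000, seed = 33)
  # feed the converged output back in: the kept set must not move
  second <- refineSites(first$sites, reg$extended, nNull = 5000, seed = 33)
  key <- function(df) sort(paste(df$region_id, df$start, df$strand))
  expect_identical(key(second$sites), key(first$sites))
})

test_that("the z-score filter is a plain threshold", {
  sites <- emptySiteTable()
  sites <- rbind(sites, data.frame(tf_id = "t", region_id = "r",
                                   start = 0L, end = 14L, strand = "+",
                                   sequence = consensusSite("TG"),
                                   score = 1, zscore = c(3, 5, 7),
                                   confidence = NA_real_))
  expect_identical(nrow(zscoreFilter(sites, -Inf)), 3L)
  expect_identical(nrow(zscoreFilter(sites, 5)), 2L)
  expect_identical(nrow(zscoreFilter(sites, 8)), 0L)
  # brute-force agreement on a mixed set
  zmin <- 4.5
  expect_identical(zscoreFilter(sites, zmin)$zscore,
                   sites$zscore[sites$zscore >= zmin])
})
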