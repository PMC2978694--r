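test_that("quartets read half sites on the right strands", {
  # perfect palindrome: both semisequences equal
  q <- siteQuartet(consensusSite("TG"))
  expect_identical(q$left, "TG")
  expect_identical(q$right, "TG")
  expect_true(q$palindromic)

  # mixed site: unordered pair
  m <- siteQuartet(consensusSite("TG", "CA"))
  expect_identical(m$left, "TG")
  expect_identical(m$right, "CA")
  expect_identical(m$pair, c("CA", "TG"))
  expect_false(m$palindromic)

  # strand invariance: a site and its reverse complement share the quartet
  s <- consensusSite("GA", "TT")
  expect_identical(siteQuartet(s)$pair, siteQuartet(revComp(s))$pair)

  expect_error(siteQuartet("ACGTACGTACGT"), "14")
  # 15-bp site with a central insertion normalizes to 14
  s15 <- paste0(substr(s, 1, 7), "A", substr(s, 8, 14))
  expect_identical(siteQuartet(dropCentralInsertion(s15))$pair,
                   siteQuartet(s)$pair)
})

test_that("the combination space has 136 cells and F counts every site once", {
  keys <- quartetCombinations()
  expect_length(keys, 136L)
  parts <- strsplit(keys, "|", fixed = TRUE)
  expect_identical(sum(vapply(parts, function(p) p[1] == p[2], logical(1))),
                   16L)  # diagonal
  expect_identical(sum(vapply(parts, function(p) p[1] != p[2], logical(1))),
                   120L)

  F3 <- buildCombinationMatrix(rep(consensusSite("TG"), 3))
  expect_identical(unname(F3[["TG|TG"]]), 3L)
  expect_identical(sum(F3), 3L)

  # exhaustive-enumeration oracle on a large random set
  set.seed(91)
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  sites <- replicate(10000, consensusSite(sample(dinucs, 1),
                                          sample(dinucs, 1)))
  F <- buildCombinationMatrix(sites)
  expect_identical(sum(F), 10000L)
  oracle <- oracleQuartetCounts(sites)
  for (k in names(oracle))
    expect_identical(unname(F[[k]]), unname(as.integer(oracle[[k]])))

  # strand invariance of F
  Frc <- buildCombinationMatrix(vapply(sites[1:500], revComp, character(1)))
  expect_identical(as.integer(Frc), as.integer(
    buildCombinationMatrix(sites[1:500])))
})

test_that("significance testing flags concentrated cells and not expectation-level ones", {
  # all 100 sites in one palindromic cell (expected p = 1/256)
  F <- buildCombinationMatrix(rep(consensusSite("TG"), 100))
  S <- significantCombinations(F)
  expect_true(S$significant[S$combo == "TG|TG"])
  # oracle: binomial upper tail for that cell
  pOracle <- pbinom(99, 100, 1 / 256, lower.tail = FALSE)
  expect_equal(S$p[S$combo == "TG|TG"], pOracle)

  # counts spread at expectation: nothing significant
  set.seed(13)
  dinucs <- sort(names(backgroundDinucleotides()))
  unif <- replicate(256, consensusSite(sample(dinucs, 1), sample(dinucs, 1)))
  Su <- significantCombinations(buildCombinationMatrix(unif))
  expect_lte(sum(Su$significant), 2L)  # FDR-level false positives at most

  # a single site cannot reach significance
  S1 <- significantCombinations(buildCombinationMatrix(consensusSite("AA")))
  expect_identical(sum(S1$significant), 0L)
  expect_equal(S1$p[S1$combo == "AA|AA"], 1 - (1 - 1 / 256)^1)
})

test_that("planted degeneracy scenarios are classified correctly at n = 40", {
  classify1 <- function(scenario, sd) {
    sites <- generateDegeneracySites(scenario, 40, c("TG", "CA"), seed = sd)
    F <- buildCombinationMatrix(sites)
    S <- significantCombinations(F)
    scenarioLabel(classifyDegeneracies(S))
  }
  labels <- list(exclusive = "extrinsic",
                 both_high_affinity = "sym_intrinsic",
                 preferential = "asym_intrinsic")
  for (sc in names(labels)) {
    acc <- mean(vapply(1:50, function(sd) classify1(sc, sd) == labels[[sc]],
                       logical(1)))
    expect_gte(acc, 0.9)
  }

  # asymmetric case recovers the correct dominant palindrome
  sites <- generateDegeneracySites("preferential", 60, c("TG", "CA"),
                                   seed = 404)
  rel <- classifyDegeneracies(
    significantCombinations(buildCombinationMatrix(sites)))
  asym <- rel[rel$type == "asym_intrinsic", ]
  expect_gte(nrow(asym), 1L)
  expect_identical(unique(asym$semiseq_b), "TG")
})

test_that("no pair is both extrinsic and intrinsic, and power grows with n", {
  # invariant sweep over mixed random scenarios
  for (sd in 1:20) {
    sc <- c("exclusive", "both_high_affinity", "preferential")[sd %% 3 + 1]
    sites <- generateDegeneracySites(sc, 30, c("TT", "GG"), seed = sd)
    rel <- classifyDegeneracies(
      significantCombinations(buildCombinationMatrix(sites)))
    if (nrow(rel)) {
      key <- paste(pmin(rel$semiseq_a, rel$semiseq_b),
                   pmax(rel$semiseq_a, rel$semiseq_b))
      ext <- unique(key[rel$type == "extrinsic"])
      intr <- unique(key[rel$type != "extrinsic"])
      expect_length(intersect(ext, intr), 0L)
    }
  }

  # recovery rate is non-decreasing in the number of sites
  accAt <- function(n) {
    mean(vapply(1:30, function(sd) {
      sites <- generateDegeneracySites("preferential", n, c("TG", "CA"),
                                       seed = 7000 + sd)
      S <- significantCombinations(buildCombinationMatrix(sites))
      scenarioLabel(classifyDegeneracies(S)) == "asym_intrinsic"
    }, logical(1)))
  }
  acc <- vapply(c(10, 40, 160), accAt, numeric(1))
  expect_true(all(diff(acc) >= 0))
})
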