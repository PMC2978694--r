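test_that("generated families carry the planted residues at the fixed columns", {
  code <- plantedCode(c(KA = "TG"))
  fam <- generateFamily(1, 3, code, seed = 7)
  aln <- alignedSeqs(fam$alignment)
  expect_length(aln, 3L)
  expect_true(all(substr(aln, 15, 20) == "KATVSR"))
  expect_true(all(substr(aln, 51, 51) == "A"))
  expect_true(all(substr(aln, 54, 54) == "L"))

  two <- generateFamily(2, 5, testCode(), seed = 1)
  expect_length(two$alignment, 10L)
  expect_identical(alignmentWidth(two$alignment), 71L)

  # determinism: same seed, byte-identical output
  again <- generateFamily(2, 5, testCode(), seed = 1)
  expect_identical(alignedSeqs(again$alignment), alignedSeqs(two$alignment))
  expect_identical(again$classMap, two$classMap)

  expect_error(generateFamily(3, 2, testCode(), seed = 1), "distinct")
})

test_that("region generation respects site_rate, coordinates and the site backbone", {
  code <- testCode()
  fam <- generateFamily(2, 4, code, seed = 2)

  none <- generateRegions(fam$classMap, code, siteRate = 0, regionLen = 100,
                          seed = 3)
  expect_identical(nrow(none$truth), 0L)
  expect_true(all(nchar(none$strict) == 100L))
  expect_true(all(nchar(none$extended) == 250L))

  all <- generateRegions(fam$classMap, code, siteRate = 1, regionLen = 150,
                         seed = 4)
  expect_identical(nrow(all$truth), nrow(fam$classMap))
  # planted sites lie fully inside their regions and match the slice
  for (i in seq_len(nrow(all$truth))) {
    tr <- all$truth[i, ]
    expect_identical(substr(all$strict[[tr$region_id]], tr$start + 1,
                            tr$start + 14), tr$site_seq)
    expect_identical(substr(all$extended[[tr$region_id]],
                            tr$start_extended + 1, tr$start_extended + 14),
                     tr$site_seq)
    expect_identical(substr(tr$site_seq, 2, 2), "G")   # NT-6
    expect_identical(substr(tr$site_seq, 7, 8), "CG")  # central CG
  }
  # all KA-class quartets are the planted palindrome
  ka <- all$truth[grepl("KA", all$truth$tf_id), ]
  expect_true(all(ka$d_left == "TG" & ka$d_right == "TG"))
})

test_that("asymmetric intrinsic planting hits the dominant-palindrome fraction", {
  code <- plantedCode(
    data.frame(aa_pair = "KA", semiseq = c("TG", "TA"), weight = c(0.8, 0.2)),
    degeneracy = list(KA = list(type = "asym_intrinsic", dominant = "TG",
                                minor = "TA", dominant_prob = 0.8)))
  classMap <- data.frame(tf_id = sprintf("tf_KA_%04d", 1:10000),
                         aa_pair = "KA")
  reg <- generateRegions(classMap, code, siteRate = 1, regionLen = 50,
                         seed = 9)
  domFrac <- mean(reg$truth$d_left == "TG" & reg$truth$d_right == "TG")
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(domFrac - 0.8), 3 * se)
})

test_that("planted quartet frequencies follow the code weights (chi-square)", {
  # sym_intrinsic: half sites drawn independently with the entry weights
  code <- plantedCode(
    data.frame(aa_pair = "KA", semiseq = c("TG", "CA"), weight = c(0.6, 0.4)))
  classMap <- data.frame(tf_id = sprintf("tf_KA_%04d", 1:10000),
                         aa_pair = "KA")
  rejected <- vapply(1:6, function(sd) {
    reg <- generateRegions(classMap, code, siteRate = 1, regionLen = 50,
                           seed = sd)
    obs <- table(factor(paste0(reg$truth$d_left, reg$truth$d_right),
                        levels = c("TGTG", "TGCA", "CATG", "CACA")))
    expected <- c(0.36, 0.24, 0.24, 0.16)
    suppressWarnings(
      stats::chisq.test(as.numeric(obs), p = expected)$p.value) < 0.01
  }, logical(1))
  expect_lte(sum(rejected), 1L)
})

test_that("degeneracy benchmark scenarios have the designed mixture structure", {
  # exclusive: no mixtures by construction
  ex <- generateDegeneracySites("exclusive", 100, c("TG", "CA"), seed = 1)
  expect_identical(sum(attr(ex, "config") %in% c("M1", "M2")), 0L)

  # both_high_affinity at equal weights: mixture fraction 1/2
  # (two ordered mixtures among four equiprobable half-site pairings)
  bh <- generateDegeneracySites("both_high_affinity", 10000, c("TG", "CA"),
                                seed = 2)
  mixFrac <- mean(attr(bh, "config") %in% c("M1", "M2"))
  expect_lt(abs(mixFrac - 0.5), 4 * sqrt(0.25 / 10000))

  # preferential with dominant_prob 1 degenerates to a mixture-free set
  pr <- generateDegeneracySites("preferential", 200, c("TG", "CA"),
                                dominantProb = 1, seed = 3)
  expect_identical(sum(attr(pr, "config") %in% c("M1", "M2")), 0L)

  # site sequences are consistent with their configuration labels
  q <- siteQuartet(bh[[1]])
  cfg <- as.character(attr(bh, "config")[1])
  expectPair <- switch(cfg, P1 = c("TG", "TG"), P2 = c("CA", "CA"),
                       sort(c("TG", "CA")))
  expect_identical(q$pair, sort(expectPair))
})

test_that("downstream regions and minus-strand planting are supported", {
  code <- testCode()
  fam <- generateFamily(2, 3, code, seed = 41)
  reg <- generateRegions(fam$classMap, code, siteRate = 1, regionLen = 100,
                         seed = 42, downstream = TRUE, minusStrandRate = 0.5)
  expect_length(reg$strict, 2L * nrow(fam$classMap))
  expect_true(all(c(paste0(fam$classMap$tf_id, "_up"),
                    paste0(fam$classMap$tf_id, "_down")) %in%
                    names(reg$strict)))
  # minus-strand truth rows carry the motif on the sense reading; the
  # region slice holds its reverse complement
  minus <- reg$truth[reg$truth$strand == "-", ]
  expect_gt(nrow(minus), 0L)
  for (i in seq_len(nrow(minus))) {
    sl <- substr(reg$strict[[minus$region_id[i]]], minus$start[i] + 1,
                 minus$start[i] + 14)
    expect_identical(sl, revComp(minus$site_seq[i]))
  }
})

test_that("mononucleotide shuffles preserve composition and determinism", {
  expect_identical(shuffleRegion("AAAA", seed = 1), "AAAA")
  s <- "ACGTACGTTTGCAN"
  sh <- shuffleRegion(s, seed = 1)
  expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_identical(shuffleRegion(s, seed = 1), sh)
  expect_error(shuffleRegion("ACGU"), "A,C,G,T,N")
})
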