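test_that("length/core filtering keeps the inclusive boundary cases", {
  recs <- domainRecords(
    id = c("d49", "d50", "d70", "d71"),
    aligned_seq = vapply(c(49, 50, 70, 71), function(n)
      paste0(strrep("K", n), strrep("-", 71 - n)), character(1)))
  kept <- filterDomains(recs, lengthRange = c(50, 70), requireCore = FALSE)
  expect_setequal(kept$id, c("d50", "d70"))

  recs$has_core_domain <- c(TRUE, FALSE, TRUE, TRUE)
  kept <- filterDomains(recs, lengthRange = c(45, 75), requireCore = TRUE)
  expect_false("d50" %in% kept$id)

  empty <- filterDomains(recs[0, ], lengthRange = c(45, 75))
  expect_identical(nrow(empty), 0L)
})

test_that("deduplication collapses identical sequences to the first sorted id", {
  recs <- domainRecords(id = c("B", "A", "C"),
                        aligned_seq = c("KKAA", "KKAA", "KYAA"))
  expect_message(out <- dedupeDomains(recs), "removed 1")
  expect_setequal(out$id, c("A", "C"))
  expect_identical(attr(out, "n_removed"), 1L)

  distinct <- domainRecords(id = c("x", "y"), aligned_seq = c("AAAA", "CCCC"))
  expect_identical(nrow(dedupeDomains(distinct)), 2L)
})

test_that("deduplication matches a hash-set oracle on a noisy fixture", {
  set.seed(31)
  pool <- replicate(40, paste(sample(c("K", "A", "Y", "Q", "T"), 12,
                                     replace = TRUE), collapse = ""))
  seqs <- sample(pool, 300, replace = TRUE)  # heavy duplication
  recs <- domainRecords(id = sprintf("d%03d", 1:300), aligned_seq = seqs)
  out <- suppressMessages(dedupeDomains(recs))
  expect_identical(nrow(out), length(unique(seqs)))
  expect_setequal(out$raw_seq, unique(seqs))
})

test_that("gap-dominated columns are dropped with a strict > threshold", {
  # 10 sequences; column gap fractions: 0.9, 0.8, 0.0
  cols <- cbind(c(rep("-", 9), "K"), c(rep("-", 8), "A", "A"), rep("Y", 10))
  seqs <- apply(cols, 1, paste, collapse = "")
  names(seqs) <- sprintf("s%02d", 1:10)
  out <- dropGappyColumns(seqs, maxGapFraction = 0.80)
  expect_identical(out$keptColumns, c(2L, 3L))  # exactly 80% is kept
  expect_identical(alignmentWidth(out$alignment), 2L)

  gapless <- dropGappyColumns(c(a = "KAY", b = "KAY"))
  expect_identical(gapless$keptColumns, 1:3)
})

test_that("recognition residues are read from the fixed frame, gaps tolerated", {
  fam <- generateFamily(1, 2, plantedCode(c(KA = "TG")), seed = 3)
  res <- recognitionResidues(fam$alignment)
  expect_identical(unname(res[1, c("col17", "col18", "col19", "col20")]),
                   c("T", "V", "S", "R"))
  expect_identical(unname(res[, "col15"]), c("K", "K"))

  single <- paste0(strrep("K", 14), "-", strrep("K", 56))
  got <- recognitionResidues(single, columns = c(15, 16))
  expect_identical(unname(got), c("-", "K"))
  expect_error(recognitionResidues(single, columns = 72), "outside")
})

test_that("class partitioning restricts, partitions and orders deterministically", {
  mk <- function(p15, p16, helix = "TVSR") {
    paste0(strrep("G", 14), p15, p16, helix, strrep("G", 51))
  }
  seqs <- c(t1 = mk("K", "A"), t2 = mk("K", "A"), t3 = mk("Y", "Q"),
            t4 = mk("K", "A", "TVSG"))
  aln <- DomainAlignment(seqs)
  classes <- partitionClasses(aln)
  expect_identical(names(classes), c("KA", "YQ"))
  expect_setequal(classes$KA$members, c("t1", "t2"))
  expect_identical(classes$YQ$members, "t3")
  # excluded by the helix restriction
  expect_false("t4" %in% unlist(lapply(classes, `[[`, "members")))

  # disjoint cover of the restricted set
  cm <- attr(classes, "classMap")
  expect_identical(sort(cm$tf_id), c("t1", "t2", "t3"))
  expect_false(anyDuplicated(cm$tf_id) > 0)

  # restriction disabled: everything is partitioned
  all <- partitionClasses(aln, restrict = NULL)
  expect_identical(nrow(attr(all, "classMap")), 4L)
})

test_that("filter-dedupe-partition is idempotent on its own output", {
  fam <- generateFamily(2, 4, testCode(), seed = 8)
  recs <- domainRecords(id = fam$classMap$tf_id,
                        aligned_seq = alignedSeqs(fam$alignment))
  once <- suppressMessages(
    dedupeDomains(filterDomains(recs, c(45, 75), requireCore = FALSE)))
  twice <- suppressMessages(
    dedupeDomains(filterDomains(once, c(45, 75), requireCore = FALSE)))
  expect_identical(once$id, twice$id)
  expect_identical(once$raw_seq, twice$raw_seq)
})
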