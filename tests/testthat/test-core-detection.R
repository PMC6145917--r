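# A small crafted dataset: lineage "core" is an identical 100-mer present in
# all samples; lineage "priv" gives each sample a private unrelated sequence.
craftedDataset <- function(nSamples = 3, coreReads = 2) {
  set.seed(101)
  core_seq <- rndDNA(100)
  ids <- character(0); seqs <- character(0); samples <- character(0)
  for (s in seq_len(nSamples)) {
    sid <- paste0("S", s)
    ids <- c(ids, sprintf("%s_c%d", sid, seq_len(coreReads)),
             sprintf("%s_p1", sid))
    seqs <- c(seqs, rep(core_seq, coreReads), rndDNA(100))
    samples <- c(samples, rep(sid, coreReads + 1))
  }
  makeDataset(ids, seqs, samples)
}

test_that("masking recomputes counts over unclaimed records only", {
  ds <- craftedDataset()
  res <- ladderCluster(ds, 0.97)[[1]]
  tbl <- buildOTUTable(res, ds)

  # empty claim: identity
  expect_identical(as.matrix(otuCounts(maskTable(tbl, res, character(0), ds))),
                   as.matrix(otuCounts(tbl)))

  # claim all members of the shared OTU: its column zeroes, others unchanged
  core_otu <- names(which(Matrix::colSums(otuCounts(tbl) > 0) == 3))
  claimed <- names(res@originMap)[res@originMap == core_otu]
  masked <- maskTable(tbl, res, claimed, ds)
  expect_equal(otuIds(masked), otuIds(tbl))     # ids stable, column retained
  expect_true(all(otuCounts(masked)[, core_otu] == 0))
  other <- setdiff(otuIds(tbl), core_otu)
  expect_equal(as.matrix(otuCounts(masked))[, other],
               as.matrix(otuCounts(tbl))[, other])

  # claim part of the OTU across two samples: totals drop by exactly the
  # intersection size (verified by brute-force recount over records)
  part <- claimed[1:3]
  masked2 <- maskTable(tbl, res, part, ds)
  brute <- table(factor(ds@sampleIds[!(seqIds(ds) %in% part)],
                        levels = sampleNames(ds)),
                 factor(unname(originMap(res)[seqIds(ds)[
                   !(seqIds(ds) %in% part)]]), levels = otuIds(tbl)))
  expect_equal(unname(as.matrix(otuCounts(masked2))),
               unname(as.matrix(as.data.frame.matrix(brute))))
  expect_equal(sum(otuCounts(tbl)) - sum(otuCounts(masked2)), length(part))
})

test_that("core detection applies the ceiling prevalence rule", {
  m <- matrix(c(3, 1, 2,   2, 5, 0,   0, 0, 4), nrow = 3,
              dimnames = list(paste0("S", 1:3), c("all", "two", "one")))
  tbl <- makeTable(m)
  expect_equal(detectCoreAtLevel(tbl, 1), "all")
  # ceil(0.6 * 3) = 2 samples needed
  expect_setequal(detectCoreAtLevel(tbl, 0.6), c("all", "two"))
  # an all-zero column is never core
  m2 <- cbind(m, zero = c(0, 0, 0))
  expect_false("zero" %in% detectCoreAtLevel(makeTable(m2), 0.1))
})

test_that("a universally shared exact sequence yields exactly one 0.97 core
           and nothing below", {
  ds <- craftedDataset()
  core <- runDynamicCore(ds, thresholds = c(0.97, 0.90, 0.80))
  expect_equal(coreCount(core), 1L)
  co <- coreOTUs(core)[[1]]
  expect_equal(co@detectionThreshold, 0.97)
  # it claims exactly the six shared reads (2 per sample x 3 samples)
  expect_equal(length(co@maskedMemberIds), 6L)
  expect_true(all(grepl("_c", co@maskedMemberIds)))
  expect_equal(unname(co@perSampleCounts), rep(2, 3))
})

test_that("fully private per-sample sequences yield no cores at any level", {
  set.seed(55)
  ids <- sprintf("S%d_%d", rep(1:3, each = 4), rep(1:4, 3))
  seqs <- vapply(seq_along(ids), function(i) rndDNA(120), character(1))
  ds <- makeDataset(ids, seqs, rep(paste0("S", 1:3), each = 4))
  core <- runDynamicCore(ds)
  expect_equal(coreCount(core), 0L)
})

test_that("two planted lineages are recovered at their characteristic
           depths with disjoint memberships", {
  specs <- list(
    lineageSpec("shallow", intraDivergence = 0.02),
    lineageSpec("deep", intraDivergence = 0.10)
  )
  sim <- simulateDataset(specs, nSubjects = 6, depthPerSubject = 80,
                         seed = 31)
  core <- runDynamicCore(sim$dataset)
  ev <- evaluateRecovery(core, sim$truth)
  expect_setequal(ev$recovered, c("shallow", "deep"))
  df <- ev$perCore
  expect_equal(unique(df$threshold[df$lineage == "shallow"]), 0.97)
  expect_true(all(df$threshold[df$lineage == "deep"] < 0.97))
  # masked memberships disjoint across all cores
  members <- unlist(lapply(coreOTUs(core), function(x) x@maskedMemberIds))
  expect_false(anyDuplicated(members) > 0)
})

test_that("datasets with fewer than two samples are rejected", {
  ds <- makeDataset(c("a1", "a2"), rep(strrep("ACGT", 25), 2), c("A", "A"))
  expect_error(runDynamicCore(ds), "2 samples")
})

test_that("lowering prevalence never removes a core found at higher
           prevalence", {
  set.seed(77)
  for (rep in 1:5) {
    m <- matrix(rpois(6 * 10, 0.8), nrow = 6,
                dimnames = list(paste0("S", 1:6), paste0("o", 1:10)))
    tbl <- makeTable(m)
    hi <- detectCoreAtLevel(tbl, 1)
    for (prev in c(0.8, 0.6, 0.4)) {
      lo <- detectCoreAtLevel(tbl, prev)
      expect_true(all(hi %in% lo))
      hi <- lo
    }
  }
})

test_that("the recluster-after-mask mode agrees with masking on crafted
           structure", {
  ds <- craftedDataset(nSamples = 4, coreReads = 3)
  a <- runDynamicCore(ds, thresholds = c(0.97, 0.9, 0.8))
  b <- runDynamicCore(ds, thresholds = c(0.97, 0.9, 0.8), recluster = TRUE)
  expect_equal(coreCount(a), coreCount(b))
  expect_setequal(coreOTUs(a)[[1]]@maskedMemberIds,
                  coreOTUs(b)[[1]]@maskedMemberIds)
})
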