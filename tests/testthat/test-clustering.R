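test_that("greedy clustering groups identical sequences and splits at the
           threshold", {
  s <- strrep("ACGT", 25)                 # 100-mer
  r <- greedyCluster(c("a", "b", "c"), c(s, s, s), threshold = 0.97)
  expect_equal(length(otuIds(r)), 1L)
  expect_equal(sort(r@members[[1]]), c("a", "b", "c"))
  expect_equal(unname(originMap(r)), rep(otuIds(r), 3))

  # two sequences at identity 0.95: split at 0.97, merged at 0.90
  set.seed(3)
  s2 <- mutateSeq(s, 5)
  expect_equal(pairwiseIdentity(s, s2), 0.95)
  split <- greedyCluster(c("a", "b"), c(s, s2), threshold = 0.97)
  expect_equal(length(otuIds(split)), 2L)
  merged <- greedyCluster(c("a", "b"), c(s, s2), threshold = 0.90)
  expect_equal(length(otuIds(merged)), 1L)
})

test_that("greedy clustering honours weight ordering, id tie-breaks and
           rejects duplicate ids", {
  s <- strrep("ACGT", 25)
  set.seed(5)
  s2 <- mutateSeq(s, 2)                   # 0.98 to s
  # heavier item becomes the centroid even if listed later
  r <- greedyCluster(c("light", "heavy"), c(s, s2), weights = c(1, 5),
                     threshold = 0.97)
  expect_equal(unname(r@representativeIds[1]), "heavy")
  # equal weights: ascending id founds first
  r2 <- greedyCluster(c("zz", "aa"), c(s, s2), threshold = 0.97)
  expect_equal(unname(r2@representativeIds[1]), "aa")
  expect_error(greedyCluster(c("a", "a"), c(s, s), threshold = 0.9),
               "duplicate")
  # empty input is a valid degenerate case
  e <- greedyCluster(character(0), character(0), numeric(0), threshold = 0.9)
  expect_equal(length(otuIds(e)), 0L)
})

test_that("clustering output is identical to the reference implementation",
{
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    base <- rndDNA(sample(80:150, 1))
    seqs <- vapply(seq_len(n), function(i) {
      if (i %% 3 == 0) rndDNA(sample(80:150, 1))
      else mutateSeq(base, sample(0:12, 1))
    }, character(1))
    ids <- sprintf("q%03d", sample(n))
    w <- sample(1:4, n, replace = TRUE)
    thr <- sample(c(0.97, 0.9, 0.85), 1)
    res <- greedyCluster(ids, seqs, weights = w, threshold = thr)
    ref <- refGreedyCluster(ids, seqs, weights = w, threshold = thr)
    expectMatchesReference(res, ref, thr)
  }
})

test_that("chained clustering composes origin maps and conserves members", {
  set.seed(8)
  base <- rndDNA(120)
  ids <- sprintf("r%02d", 1:30)
  seqs <- vapply(1:30, function(i) mutateSeq(base, sample(0:18, 1)),
                 character(1))
  samples <- rep(c("A", "B", "C"), each = 10)
  ds <- makeDataset(ids, seqs, samples)

  ladder <- ladderCluster(ds, thresholds = c(0.97, 0.96, 0.95))
  expect_error(chainCluster(ladder[[3]], 0.95), "strictly below")

  # origin map at the lowest level equals the explicit composition of the
  # three per-step maps
  l1 <- ladder[[1]]; l2 <- ladder[[2]]; l3 <- ladder[[3]]
  step2 <- setNames(unname(l2@originMap[unname(l1@representativeIds)]),
                    otuIds(l1))
  step3 <- setNames(unname(l3@originMap[unname(l2@representativeIds)]),
                    otuIds(l2))
  composed <- step3[step2[l1@originMap]]
  expect_equal(unname(l3@originMap[names(l1@originMap)]), unname(composed))

  # conservation at every level: the origin map stays total over the input
  # and surjective onto the level's OTUs
  for (res in ladder) {
    expect_setequal(names(res@originMap), ids)
    expect_setequal(unique(unname(res@originMap)), otuIds(res))
    expect_equal(sum(table(res@originMap)), length(ids))
  }

  # single-OTU chaining keeps the origin domain
  one <- greedyCluster("x", strrep("ACGT", 30), threshold = 0.97)
  chained <- chainCluster(one, 0.90)
  expect_equal(length(otuIds(chained)), 1L)
  expect_equal(names(chained@originMap), names(one@originMap))
})

test_that("the default ladder has 23 descending levels and OTU counts are
           non-increasing", {
  grid <- defaultThresholds()
  expect_equal(length(grid), 23L)
  expect_equal(grid[1], 0.97)
  expect_equal(grid[23], 0.75)
  expect_true(all(diff(grid) < 0))

  sim <- simulateDataset(defaultLineageSpecs(2, 3), nSubjects = 3,
                         depthPerSubject = 40, seed = 2)
  ladder <- ladderCluster(sim$dataset)
  expect_equal(length(ladder), 23L)
  counts <- vapply(ladder, function(r) length(otuIds(r)), integer(1))
  expect_true(all(diff(counts) <= 0))

  # single-sequence dataset: every level has exactly one OTU
  ds1 <- makeDataset(c("a_1", "b_1"), rep(strrep("ACGT", 25), 2),
                     c("a", "b"))
  l1 <- ladderCluster(ds1)
  expect_true(all(vapply(l1, function(r) length(otuIds(r)),
                         integer(1)) == 1L))
  expect_error(ladderCluster(ds1, thresholds = c(0.9, 0.97)), "descending")
})

test_that("members satisfy the greedy identity guarantee to their
           representative", {
  set.seed(13)
  base <- rndDNA(100)
  ids <- sprintf("s%02d", 1:25)
  seqs <- vapply(1:25, function(i) mutateSeq(base, sample(0:10, 1)),
                 character(1))
  r <- greedyCluster(ids, seqs, threshold = 0.95)
  for (otu in otuIds(r)) {
    rep_seq <- as.character(r@representativeSeqs[[otu]])
    for (mid in r@members[[otu]]) {
      member_seq <- seqs[match(mid, ids)]
      expect_gte(pairwiseIdentity(member_seq, rep_seq), 0.95)
    }
  }
})

test_that("OTU tables count records per sample and conserve the total", {
  ds <- makeDataset(sprintf("r%d", 1:5), rep(strrep("ACGT", 25), 5),
                    rep("S1", 5))
  res <- ladderCluster(ds, 0.97)[[1]]
  tbl <- buildOTUTable(res, ds)
  expect_equal(as.numeric(otuCounts(tbl)), 5)

  sim <- simulateDataset(defaultLineageSpecs(2, 2), nSubjects = 3,
                         depthPerSubject = 30, seed = 4)
  res <- ladderCluster(sim$dataset, 0.97)[[1]]
  tbl <- buildOTUTable(res, sim$dataset)
  expect_equal(sum(otuCounts(tbl)), length(sim$dataset))

  # an OTU shared by two samples has two nonzero cells in its column
  ds2 <- makeDataset(c("x1", "x2", "y1"),
                     c(strrep("ACGT", 25), strrep("ACGT", 25),
                       strrep("TTGA", 25)),
                     c("S1", "S2", "S1"))
  res2 <- ladderCluster(ds2, 0.97)[[1]]
  tbl2 <- buildOTUTable(res2, ds2)
  shared <- which(Matrix::colSums(otuCounts(tbl2) > 0) == 2)
  expect_equal(length(shared), 1L)
})

test_that("clustering is deterministic across repeated runs", {
  set.seed(17)
  base <- rndDNA(90)
  ids <- sprintf("d%02d", 1:20)
  seqs <- vapply(1:20, function(i) mutateSeq(base, sample(0:15, 1)),
                 character(1))
  r1 <- greedyCluster(ids, seqs, threshold = 0.92)
  r2 <- greedyCluster(ids, seqs, threshold = 0.92)
  expect_identical(originMap(r1), originMap(r2))
  expect_identical(r1@representativeIds, r2@representativeIds)
})
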