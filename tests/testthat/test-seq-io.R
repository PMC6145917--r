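test_that("FASTA reading attributes samples from qiime-style headers", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">S1_00042", "acgtacgtacgtacgtacgt",
               ">S1_00043", "ACGTACGTACGTACGTACGA",
               ">S2_00001", "ACGTACGTACGTACGTACGN"), fa)
  ds <- readFastaWithSamples(fa, minLength = 10)
  expect_s4_class(ds, "AmpliconDataset")
  expect_equal(seqIds(ds), c("S1_00042", "S1_00043", "S2_00001"))
  expect_equal(sampleIds(ds), c("S1", "S1", "S2"))
  expect_equal(sampleNames(ds), c("S1", "S2"))
  # lowercase uppercased, N retained
  expect_equal(as.character(sequences(ds)[[1]]), "ACGTACGTACGTACGTACGT")
  expect_true(grepl("N", as.character(sequences(ds)[[3]])))
  unlink(fa)
})

test_that("map-file attribution works and missing ids are hard errors", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTACGTACGT", ">r2", "ACGTACGTACGA",
               ">r3", "ACGTACGTACGC"), fa)
  map <- tempfile(fileext = ".tsv")
  writeLines(c("r1\tsampleA", "r2\tsampleB", "r3\tsampleA"), map)
  ds <- readFastaWithSamples(fa, sampleMap = map, headerStyle = "map_file",
                             minLength = 5)
  expect_equal(length(ds), 3L)
  expect_equal(sampleNames(ds), c("sampleA", "sampleB"))
  expect_equal(unname(sampleIds(ds)), c("sampleA", "sampleB", "sampleA"))

  # drop one entry: the error must identify the offending id
  writeLines(c("r1\tsampleA", "r3\tsampleA"), map)
  expect_error(readFastaWithSamples(fa, sampleMap = map,
                                    headerStyle = "map_file", minLength = 5),
               "r2")
  unlink(c(fa, map))
})

test_that("empty FASTA and short sequences are rejected at read time", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_error(readFastaWithSamples(fa), "empty")
  writeLines(c(">S1_1", "ACGT", ">S1_2", paste(rep("A", 80), collapse = "")),
             fa)
  expect_warning(ds <- readFastaWithSamples(fa, minLength = 75), "rejected")
  expect_equal(length(ds), 1L)
  unlink(fa)
})

test_that("common-depth subsampling equalizes depths deterministically", {
  set.seed(11)
  n <- c(10, 7, 12)
  ids <- unlist(lapply(seq_along(n), function(s)
    sprintf("S%d_%03d", s, seq_len(n[s]))))
  seqs <- vapply(seq_along(ids), function(i) rndDNA(80), character(1))
  samples <- rep(paste0("S", seq_along(n)), n)
  ds <- makeDataset(ids, seqs, samples)

  sub <- subsampleCommonDepth(ds, seed = 5)
  expect_true(all(sampleDepths(sub) == 7))
  # drawn records are verbatim copies of the originals
  expect_true(all(seqIds(sub) %in% seqIds(ds)))
  expect_identical(unname(as.character(sequences(sub))),
                   unname(as.character(sequences(ds))[
                     match(seqIds(sub), seqIds(ds))]))
  # determinism
  sub2 <- subsampleCommonDepth(ds, seed = 5)
  expect_identical(seqIds(sub), seqIds(sub2))
  # already at common depth: record multiset unchanged
  eq <- makeDataset(ids[1:9], seqs[1:9], rep(c("A", "B", "C"), each = 3))
  expect_identical(seqIds(subsampleCommonDepth(eq, seed = 1)), ids[1:9])
})

test_that("OTU table TSV round-trips labels, counts and threshold", {
  m <- matrix(c(5, 0, 2, 3), nrow = 2,
              dimnames = list(c("S1", "S2"), c("otuA", "otuB")))
  tbl <- makeTable(m, threshold = 0.93)
  path <- tempfile(fileext = ".tsv")
  writeOTUTable(tbl, path)
  back <- readOTUTable(path)
  expect_equal(as.matrix(otuCounts(back)), as.matrix(otuCounts(tbl)))
  expect_equal(clusterThreshold(back), 0.93)
  expect_equal(sampleIds(back), c("S1", "S2"))
  expect_equal(otuIds(back), c("otuA", "otuB"))
  # grand total preserved
  expect_equal(sum(otuCounts(back)), sum(m))
  unlink(path)
})

test_that("empty-OTU tables and sparse zeros survive the TSV round-trip", {
  m0 <- matrix(0, nrow = 3, ncol = 0,
               dimnames = list(c("S1", "S2", "S3"), character(0)))
  tbl <- makeTable(m0, threshold = 0.75)
  path <- tempfile(fileext = ".tsv")
  writeOTUTable(tbl, path)
  back <- readOTUTable(path)
  expect_equal(ncol(otuCounts(back)), 0L)
  expect_equal(clusterThreshold(back), 0.75)

  # zeros stored sparsely come back as implicit zeros
  m <- matrix(c(0, 7, 0, 0, 1, 0), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("a", "b")))
  writeOTUTable(makeTable(m), path)
  expect_equal(as.matrix(otuCounts(readOTUTable(path))), m)
  unlink(path)
})

test_that("malformed OTU tables fail with a line reference", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# threshold=0.9", "#OTU_ID\tS1\tS2", "otu1\t3"), path)
  expect_error(readOTUTable(path), "line 3")
  writeLines(c("#OTU_ID\tS1", "otu1\t3"), path)
  expect_error(readOTUTable(path), "threshold")
  unlink(path)
})

test_that("BIOM v1 JSON round-trip preserves the table", {
  m <- matrix(c(5, 1, 2, 3, 0, 4), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("x", "y")))
  tbl <- makeTable(m, threshold = 0.88)
  path <- tempfile(fileext = ".biom")
  writeOTUTable(tbl, path, format = "biom_json")
  back <- readOTUTable(path, format = "biom_json")
  expect_equal(as.matrix(otuCounts(back))[rownames(m), colnames(m)], m)
  expect_equal(clusterThreshold(back), 0.88)
  unlink(path)
})
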