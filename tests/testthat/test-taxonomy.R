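lin <- function(s) parseTaxonomyString(s)

test_that("mothur-dialect taxonomy strings parse with confidences", {
  x <- lin("Bacteria(100);Firmicutes(95);Clostridia(80);")
  expect_equal(x$taxon, c("Bacteria", "Firmicutes", "Clostridia"))
  expect_equal(x$confidence, c(1, 0.95, 0.80))
  # ranks without confidences default to 1; fraction-style confidences pass
  y <- lin("Bacteria;Bacteroidetes(0.9)")
  expect_equal(y$confidence, c(1, 0.9))
  expect_equal(nrow(lin("")), 0L)
})

test_that("consensus reproduces the three worked fixtures", {
  # full agreement
  a <- replicate(4, lin("Firmicutes(100);Clostridia(100);Lachnospiraceae(100)"),
                 simplify = FALSE)
  ca <- consensusTaxonomy(a)
  expect_equal(ca$lineage, c("Firmicutes", "Clostridia", "Lachnospiraceae"))
  expect_equal(ca$support, 1)
  expect_equal(ca$nInputs, 4L)

  # 3 of 4 at family rank: consensus stops at the family, support 0.75
  b <- c(replicate(3, lin("Firmicutes(100);Clostridia(100);Lachnospiraceae(100)"),
                   simplify = FALSE),
         list(lin("Firmicutes(100);Clostridia(100);Ruminococcaceae(100)")))
  cb <- consensusTaxonomy(b)
  expect_equal(cb$lineage[3], "Lachnospiraceae")
  expect_equal(cb$support, 0.75)

  # 2 vs 2 at family rank: truncated to the class level
  d <- c(replicate(2, lin("Firmicutes(100);Clostridia(100);Lachnospiraceae(100)"),
                   simplify = FALSE),
         replicate(2, lin("Firmicutes(100);Clostridia(100);Ruminococcaceae(100)"),
                   simplify = FALSE))
  cd <- consensusTaxonomy(d)
  expect_equal(cd$lineage, c("Firmicutes", "Clostridia"))
  expect_equal(cd$support, 1)
})

test_that("low-confidence ranks are truncated before voting", {
  a <- list(lin("Bacteria(100);Firmicutes(100);Clostridia(60)"),
            lin("Bacteria(100);Firmicutes(100);Clostridia(100)"))
  # rank 3 of the first input is below the 0.80 floor, so Clostridia gets
  # only 1 vote of 2 and the consensus stops at Firmicutes
  ca <- consensusTaxonomy(a, cutoff = 0.51)
  expect_equal(ca$lineage, c("Bacteria", "Firmicutes"))
  # with a permissive floor it is kept
  cb <- consensusTaxonomy(a, cutoff = 0.51, minConfidence = 0.5)
  expect_equal(cb$lineage[3], "Clostridia")
  expect_error(consensusTaxonomy(list()), "at least one")
})

test_that("the consensus lineage is a prefix of an input and raising the
           cutoff never deepens it", {
  set.seed(41)
  taxa <- c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
            "Streptococcaceae")
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    lins <- lapply(seq_len(n), function(i) {
      depth <- sample(2:5, 1)
      tx <- taxa[seq_len(depth)]
      if (runif(1) < 0.4) tx[depth] <- "Alternativeaceae"
      data.frame(taxon = tx, confidence = runif(depth, 0.8, 1))
    })
    prev_depth <- Inf
    for (cutoff in c(0.34, 0.51, 0.75, 0.9)) {
      cons <- consensusTaxonomy(lins, cutoff = cutoff)
      expect_lte(length(cons$lineage), prev_depth)
      prev_depth <- length(cons$lineage)
      if (length(cons$lineage)) {
        is_prefix <- vapply(lins, function(l)
          length(l$taxon) >= length(cons$lineage) &&
            identical(l$taxon[seq_along(cons$lineage)], cons$lineage),
          logical(1))
        expect_true(any(is_prefix))
        expect_gte(cons$support, cutoff)
      }
    }
  }
})

test_that("core members re-cluster into species-level representatives drawn
           from the members themselves", {
  s <- strrep("ACGT", 25)
  set.seed(61)
  s2 <- mutateSeq(s, 5)   # 5% divergent variant
  ds <- makeDataset(c("a1", "a2", "b1", "b2"), c(s, s, s2, s2),
                    c("X", "X", "Y", "Y"))
  co <- methods::new("CoreOTU", otuId = "T90_1", detectionThreshold = 0.90,
                     representativeId = "a1",
                     representativeSeq = Biostrings::DNAStringSet(s),
                     maskedMemberIds = c("a1", "a2", "b1", "b2"),
                     perSampleCounts = c(X = 2, Y = 2))
  reps <- subclusterCore(co, ds, threshold = 0.97)
  expect_equal(length(reps), 2L)            # the two 5%-apart variants
  expect_true(all(names(reps) %in% co@maskedMemberIds))

  # identical members give a single representative
  co2 <- methods::new("CoreOTU", otuId = "T97_1", detectionThreshold = 0.97,
                      representativeId = "a1",
                      representativeSeq = Biostrings::DNAStringSet(s),
                      maskedMemberIds = c("a1", "a2"),
                      perSampleCounts = c(X = 2))
  expect_equal(length(subclusterCore(co2, ds)), 1L)
})

test_that("taxonomy files round through reading and per-core consensus", {
  sim <- simulateDataset(list(lineageSpec("L1"), lineageSpec("L2")),
                         nSubjects = 3, depthPerSubject = 30, seed = 3)
  core <- runDynamicCore(sim$dataset, thresholds = c(0.97, 0.9))
  expect_gte(coreCount(core), 2L)
  # assign every read a lineage-determined taxonomy
  tax_path <- tempfile(fileext = ".taxonomy")
  fam <- c(L1 = "Lachnospiraceae", L2 = "Bacteroidaceae")
  writeLines(sprintf("%s\tBacteria(100);SomePhylum(100);%s(100);",
                     seqIds(sim$dataset),
                     fam[sim$truth@recordLineage[seqIds(sim$dataset)]]),
             tax_path)
  tax <- readTaxonomyFile(tax_path)
  tt <- coreConsensusTaxonomy(core, sim$dataset, tax)
  expect_equal(nrow(tt), coreCount(core))
  expect_true(all(tt$support == 1))
  expect_true(all(grepl("aceae$", tt$lineage)))
  unlink(tax_path)
})
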