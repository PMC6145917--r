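# Independent oracles and fixture builders shared across the test files.

# Random DNA string using the current RNG stream.
rndDNA <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Copy of a sequence with exactly k substituted positions.
mutateSeq <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# ---------------------------------------------------------------------------
# Brute-force alignment-identity oracle.
#
# Lexicographic objective (maximize score, then matches, then minimize
# columns) encoded into one number per DP cell:
#   E = (score + 5000) * 1e8 + matches * 1e4 + (4999 - columns)
# so that the numeric maximum is the lexicographic optimum. The row update
# handles the left-gap chain through a cummax transform, which makes this
# implementation structurally unlike the package's C++ kernel.
# Scoring: match +1, mismatch -1, gap -2; N matches nothing.

.enc0 <- function(s, m, co) (s + 5000) * 1e8 + m * 1e4 + (4999 - co)
.decIdentity <- function(E) {
  m <- (E %% 1e8) %/% 1e4
  co <- 4999 - (E %% 1e4)
  if (co == 0) 0 else m / co
}

# One fit-orientation pass: query q spans, reference r has free end gaps.
.oracleFitPass <- function(q, r) {
  A <- strsplit(toupper(q), "", fixed = TRUE)[[1L]]
  B <- strsplit(toupper(r), "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  g <- 2e8 + 1                       # one gap column: score -2, columns +1
  prev <- rep(.enc0(0, 0, 0), m + 1L)
  for (i in seq_len(n)) {
    mt <- A[i] == B & A[i] != "N" & B != "N"
    sub <- ifelse(mt, 1e8 + 1e4 - 1, -1e8 - 1)
    du <- pmax(prev[seq_len(m)] + sub,      # diagonal
               prev[-1L] - g)               # gap in query (up)
    du <- c(.enc0(-2 * i, 0, i), du)        # j = 0: query consumed by gaps
    k <- 0:m
    cur <- cummax(du + k * g) - k * g       # left-gap chain
    prev <- cur
  }
  max(prev)
}

# Overlap pass: free end gaps on both sequences; empty alignment allowed.
.oracleOverlapPass <- function(a, b) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  g <- 2e8 + 1
  zero <- .enc0(0, 0, 0)
  prev <- rep(zero, m + 1L)
  best <- zero
  for (i in seq_len(n)) {
    mt <- A[i] == B & A[i] != "N" & B != "N"
    sub <- ifelse(mt, 1e8 + 1e4 - 1, -1e8 - 1)
    du <- pmax(prev[seq_len(m)] + sub, prev[-1L] - g)
    du <- c(zero, du)
    k <- 0:m
    cur <- cummax(du + k * g) - k * g
    best <- max(best, cur[m + 1L])          # free trailing gaps in b
    prev <- cur
  }
  max(best, max(prev))                      # last row: free trailing in a
}

oracleIdentity <- function(a, b, endGaps = "fit") {
  E <- if (endGaps == "fit") {
    max(.oracleFitPass(a, b), .oracleFitPass(b, a))
  } else {
    .oracleOverlapPass(a, b)
  }
  .decIdentity(E)
}

# ---------------------------------------------------------------------------
# Reference greedy clusterer: a plain quadratic loop implementing the stated
# rules (decreasing weight then ascending id; best-hit centroid assignment,
# ties to the earliest centroid; new centroid otherwise).

refGreedyCluster <- function(ids, seqs, weights, threshold) {
  ord <- order(-as.numeric(weights), ids, method = "radix")
  ids <- ids[ord]; seqs <- toupper(seqs[ord])
  centroid_ids <- character(0)
  centroid_seqs <- character(0)
  member_of <- integer(length(ids))
  for (i in seq_along(ids)) {
    best_k <- 0L
    best_sim <- -1
    if (length(centroid_seqs) > 0L) {
      for (k in seq_along(centroid_seqs)) {
        sim <- pairwiseIdentity(seqs[i], centroid_seqs[k])
        if (sim > best_sim) {     # strict: earliest centroid keeps ties
          best_sim <- sim
          best_k <- k
        }
      }
    }
    if (best_k > 0L && best_sim >= threshold) {
      member_of[i] <- best_k
    } else {
      centroid_ids <- c(centroid_ids, ids[i])
      centroid_seqs <- c(centroid_seqs, seqs[i])
      member_of[i] <- length(centroid_ids)
    }
  }
  list(ids = ids, memberOf = member_of, centroidIds = centroid_ids)
}

# Compare a ClusteringResult against the reference clusterer's output.
expectMatchesReference <- function(res, ref, threshold) {
  expect_equal(length(otuIds(res)), length(ref$centroidIds))
  expect_equal(unname(res@representativeIds[otuIds(res)]), ref$centroidIds)
  got <- originMap(res)[ref$ids]
  want <- otuIds(res)[ref$memberOf]
  expect_equal(unname(got), want)
}

# ---------------------------------------------------------------------------
# Small hand-assembled datasets.

makeDataset <- function(ids, seqs, samples) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), fa)
  map <- tempfile(fileext = ".tsv")
  writeLines(paste(ids, samples, sep = "\t"), map)
  on.exit(unlink(c(fa, map)))
  readFastaWithSamples(fa, sampleMap = map, headerStyle = "map_file",
                       minLength = 1)
}

# A tiny OTUTable from a dense matrix.
makeTable <- function(m, threshold = 0.97) {
  tbl <- Matrix::Matrix(m, sparse = TRUE)
  methods::new("OTUTable",
               counts = methods::as(methods::as(methods::as(
                 tbl, "dMatrix"), "generalMatrix"), "CsparseMatrix"),
               threshold = threshold)
}

# ---------------------------------------------------------------------------
# Shared bank of seeded default-condition simulations (built lazily once;
# reused by the acceptance properties that examine many seeds).

.simBankEnv <- new.env(parent = emptyenv())

simBank <- function(nSeeds = 20) {
  key <- paste0("bank", nSeeds)
  if (is.null(.simBankEnv[[key]])) {
    .simBankEnv[[key]] <- lapply(seq_len(nSeeds), function(s) {
      sim <- simulateDataset(defaultLineageSpecs(), nSubjects = 10,
                             depthPerSubject = 500, seed = s)
      core <- runDynamicCore(sim$dataset)
      list(sim = sim, core = core)
    })
  }
  .simBankEnv[[key]]
}
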