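#' @include core-detection.R
NULL

## Uniformly permute every row's value multiset across columns (in place on a
## dense matrix) using the current RNG stream.
.shuffleRows <- function(m) {
  p <- ncol(m)
  if (p < 2L) return(m)
  for (i in seq_len(nrow(m)))
    m[i, ] <- m[i, sample.int(p)]
  m
}

#' Richness-preserving within-sample shuffle of an OTU table
#'
#' For each sample (row) independently, the full multiset of cell values --
#' zeros included -- is permuted uniformly across OTU columns. Row sums,
#' per-row nonzero counts (sample richness) and the exact per-row value
#' multisets are all preserved; only which OTU holds which value changes.
#' This is the null model used to judge how surprising the observed number
#' of core OTUs is, given each sample's richness and abundance structure.
#'
#' @param table An [OTUTable-class].
#' @param seed Integer seed; the shuffle is deterministic given it.
#' @return A shuffled [OTUTable-class] with identical labels and threshold.
#' @export
shuffleWithinSamples <- function(table, seed) {
  stopifnot(is(table, "OTUTable"))
  m <- as.matrix(otuCounts(table))
  m <- .withSeed(seed, .shuffleRows(m))
  .newOTUTable(m, table@threshold)
}

#' Permutation test for the per-level core OTU count
#'
#' Counts the OTUs meeting the prevalence rule in the observed table, then in
#' each of `nPermutations` freshly shuffled tables ([shuffleWithinSamples()]
#' mechanism), and reports the add-one empirical p-value
#' `p = (1 + #\{null >= observed\}) / (1 + nPermutations)`, i.e. the rank of
#' the observed count within its null distribution. The +1 correction keeps
#' p strictly positive.
#'
#' @param table An [OTUTable-class]; typically the per-level *masked* table,
#'   consistent with how cores are counted.
#' @param nPermutations Number of shuffled tables (default 100).
#' @param prevalence Prevalence fraction (default 1).
#' @param seed Integer seed.
#' @return A [PermutationResult-class].
#' @export
permutationCoreTest <- function(table, nPermutations = 100, prevalence = 1,
                                seed) {
  stopifnot(is(table, "OTUTable"), nPermutations >= 1)
  .stop_if(missing(seed), "permutationCoreTest requires a seed")
  need <- ceiling(prevalence * nrow(table@counts))
  count_cores <- function(m) sum(colSums(m > 0) >= need & colSums(m > 0) > 0)
  m <- as.matrix(otuCounts(table))
  observed <- count_cores(m)
  null_counts <- .withSeed(seed, {
    vapply(seq_len(nPermutations),
           function(i) count_cores(.shuffleRows(m)), numeric(1))
  })
  p <- (1 + sum(null_counts >= observed)) / (1 + nPermutations)
  new("PermutationResult",
      threshold = table@threshold,
      observedCoreCount = as.integer(observed),
      nullCounts = as.integer(null_counts),
      pValue = p,
      nPermutations = as.integer(nPermutations),
      seed = as.integer(seed))
}

#' Permutation tests across all levels of a detected core
#'
#' Applies [permutationCoreTest()] to every per-level masked table stored in
#' a [PhylogeneticCore-class], with per-level seeds derived from the master
#' seed.
#'
#' @param core A [PhylogeneticCore-class] with populated `levelTables`.
#' @param nPermutations Permutations per level (default 100).
#' @param seed Master seed.
#' @return Named list (threshold label -> [PermutationResult-class]).
#' @export
permutationTestAllLevels <- function(core, nPermutations = 100, seed) {
  stopifnot(is(core, "PhylogeneticCore"))
  .stop_if(length(core@levelTables) == 0L,
           "this PhylogeneticCore carries no level tables")
  out <- lapply(names(core@levelTables), function(lv) {
    permutationCoreTest(core@levelTables[[lv]],
                        nPermutations = nPermutations,
                        prevalence = core@prevalence,
                        seed = deriveSeed(seed, paste0("permute_", lv)))
  })
  names(out) <- names(core@levelTables)
  out
}
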