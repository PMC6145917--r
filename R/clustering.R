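#' @include utils.R
NULL

#' Pairwise sequence identity under semi-global alignment
#'
#' Computes the identity between two DNA sequences under an optimal alignment
#' with free terminal gaps (semi-global): identity = match columns /
#' alignment columns, where free terminal-gap columns are excluded and
#' internal gap columns count. Scoring is match +1, mismatch -1, gap -2.
#' Because identity can differ across co-optimal alignments, the alignment is
#' chosen by a fully deterministic rule: maximize score, then match count,
#' then prefer the fewest alignment columns. `N` never matches, including
#' against another `N`. The function is symmetric and `pairwiseIdentity(a, a)`
#' is 1.
#'
#' Two end-gap modes are provided. The default, `"fit"`, frees terminal gaps
#' only on the longer (reference) side: the shorter sequence must span the
#' alignment (both orientations are evaluated and the better kept, so the
#' result is symmetric). A fully contained sequence therefore scores
#' identity 1 -- which suits length-heterogeneous amplicon reads -- while two
#' unrelated sequences are forced into a spanning alignment and score their
#' true (low) identity. The `"overlap"` mode frees terminal gaps on both
#' sequences, additionally admitting suffix-prefix overlaps; on divergent
#' pairs its best-scoring alignment is often a tiny exact overlap that
#' reports a misleadingly high identity, so it is offered for comparison
#' only.
#'
#' @param a,b Non-empty DNA strings (or length-1 `DNAStringSet`/`DNAString`).
#' @param endGaps `"fit"` (default) or `"overlap"`; see Details.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwiseIdentity("ACGTACGTAC", "ACGTACGTAT")  # 0.9
#' pairwiseIdentity("CGTACGT", "AACGTACGTT")     # 1: contained, ends free
pairwiseIdentity <- function(a, b, endGaps = c("fit", "overlap")) {
  endGaps <- match.arg(endGaps)
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  .stop_if(length(a) != 1L || length(b) != 1L,
           "pairwiseIdentity takes a single pair of sequences")
  .stop_if(!nzchar(a) || !nzchar(b), "sequences must be non-empty")
  .identity_pair_cpp(a, b, endGaps == "fit")
}

## Vectorized identity of one query against many references (C++ kernel).
.identityMany <- function(query, refs, fit = TRUE) {
  .identity_many_cpp(toupper(as.character(query)),
                     toupper(as.character(refs)), fit)
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' Items are processed in order of decreasing weight, ties broken by ascending
#' id (C-locale). Each item is compared against all existing centroids; if the
#' best identity is at least `threshold` it joins that centroid's OTU (ties on
#' identity broken by the earliest-created centroid), otherwise it founds a
#' new OTU with itself as representative. OTU ids are assigned
#' `T<threshold*100>_<k>` in creation order. Fully deterministic.
#'
#' @param ids Unique item ids.
#' @param seqs Character vector (or `DNAStringSet`) of item sequences,
#'   parallel to `ids`.
#' @param weights Positive item weights (e.g. duplicate counts), parallel to
#'   `ids`; default all 1.
#' @param threshold Identity threshold in `(0, 1)`.
#' @param cache Optional environment memoizing pair identities by item id
#'   (identity does not depend on the threshold, so a ladder of clusterings
#'   over the same items shares one cache). Ids must identify sequences
#'   uniquely for the cache's lifetime.
#' @return A [ClusteringResult-class] whose `originMap` maps each input item
#'   to its OTU.
#' @export
#' @examples
#' r <- greedyCluster(c("a", "b", "c"),
#'                    c("ACGTACGTACGT", "ACGTACGTACGT", "TTTTGGGGCCCC"),
#'                    threshold = 0.97)
#' otuIds(r)
greedyCluster <- function(ids, seqs, weights = rep(1, length(ids)),
                          threshold, cache = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  .stop_if(anyDuplicated(ids) > 0L, "duplicate item ids: ",
           ids[anyDuplicated(ids)])
  .stop_if(length(seqs) != length(ids) || length(weights) != length(ids),
           "ids, seqs and weights must be parallel")
  .stop_if(any(weights < 1), "weights must be >= 1")
  stopifnot(threshold > 0, threshold <= 1)

  ord <- .orderBy(-as.numeric(weights), ids)
  ids <- ids[ord]; seqs <- seqs[ord]

  rep_ids <- character(0)
  rep_seqs <- character(0)
  assignment <- integer(length(ids))   # OTU index per processed item
  for (i in seq_along(ids)) {
    if (length(rep_seqs)) {
      if (is.null(cache)) {
        sims <- .identityMany(seqs[i], rep_seqs)
      } else {
        keys <- paste0(ids[i], "\r", rep_ids)
        sims <- unlist(mget(keys, envir = cache,
                            ifnotfound = list(NA_real_)),
                       use.names = FALSE)
        miss <- is.na(sims)
        if (any(miss)) {
          sims[miss] <- .identityMany(seqs[i], rep_seqs[miss])
          list2env(setNames(as.list(sims[miss]), keys[miss]), envir = cache)
        }
      }
      best <- which.max(sims)  # earliest centroid wins ties
      if (sims[best] >= threshold) {
        assignment[i] <- best
        next
      }
    }
    rep_ids <- c(rep_ids, ids[i])
    rep_seqs <- c(rep_seqs, seqs[i])
    assignment[i] <- length(rep_ids)
  }

  .asClusteringResult(ids, seqs, assignment, rep_ids, rep_seqs, threshold)
}

## Shared assembly of a ClusteringResult from a greedy assignment.
.asClusteringResult <- function(ids, seqs, assignment, rep_ids, rep_seqs,
                                threshold) {
  k <- length(rep_ids)
  otu_ids <- if (k) sprintf("T%d_%d", as.integer(round(threshold * 100)),
                            seq_len(k)) else character(0)
  members <- split(ids, factor(assignment, levels = seq_len(k)))
  names(members) <- otu_ids
  rss <- Biostrings::DNAStringSet(rep_seqs)
  names(rss) <- otu_ids
  new("ClusteringResult",
      threshold = threshold,
      otuIds = otu_ids,
      representativeIds = setNames(rep_ids, otu_ids),
      representativeSeqs = rss,
      members = as.list(members),
      originMap = setNames(otu_ids[assignment], ids))
}

#' Chain clustering to a lower threshold
#'
#' Multi-step OTU picking: the previous level's representative sequences are
#' clustered at the (strictly lower) new threshold, weighted by their OTUs'
#' total original-sequence counts. The returned `originMap` is the composition
#' original sequence -> previous OTU -> new OTU, and the representative of
#' each new OTU is the representative of its founding member.
#'
#' @param prev A [ClusteringResult-class] at a higher threshold.
#' @param threshold New threshold, strictly below `prev`'s.
#' @param cache Optional shared identity cache (see [greedyCluster()]).
#' @return A [ClusteringResult-class] with `originMap` over the same original
#'   sequences as `prev`.
#' @export
chainCluster <- function(prev, threshold, cache = NULL) {
  stopifnot(is(prev, "ClusteringResult"))
  .stop_if(threshold >= prev@threshold,
           "chain threshold (", threshold,
           ") must be strictly below the previous level (", prev@threshold,
           ")")
  item_ids <- unname(prev@representativeIds)          # per OTU, creation order
  item_seqs <- as.character(prev@representativeSeqs)
  w <- table(factor(prev@originMap, levels = prev@otuIds))
  res <- greedyCluster(item_ids, item_seqs,
                       weights = as.numeric(w), threshold = threshold,
                       cache = cache)
  # compose: original seq -> prev OTU -> rep item -> new OTU
  prev_to_new <- setNames(
    unname(res@originMap[unname(prev@representativeIds)]), prev@otuIds)
  res@originMap <- setNames(unname(prev_to_new[prev@originMap]),
                            names(prev@originMap))
  validObject(res)
  res
}

#' Cluster a dataset along a descending threshold ladder
#'
#' The first (highest) threshold clusters the dereplicated unique sequences
#' of the dataset, weighted by duplicate count; the item id of a unique
#' sequence is the id of its first occurrence in dataset order. Every
#' subsequent threshold chains from the previous level via [chainCluster()],
#' so OTU counts are non-increasing down the ladder.
#'
#' @param dataset An [AmpliconDataset-class].
#' @param thresholds Strictly descending grid in `(0, 1)`; default all 0.01
#'   steps from 0.97 down to 0.75 (23 levels, both endpoints evaluated).
#' @return Named list (formatted threshold -> [ClusteringResult-class]).
#' @export
ladderCluster <- function(dataset,
                          thresholds = defaultThresholds()) {
  stopifnot(is(dataset, "AmpliconDataset"))
  .stop_if(length(thresholds) == 0L, "empty threshold grid")
  .stop_if(any(diff(thresholds) >= 0),
           "thresholds must be strictly descending")
  stopifnot(all(thresholds > 0 & thresholds < 1))

  seqs <- as.character(dataset@sequences)
  first_idx <- which(!duplicated(seqs))
  uniq_seqs <- seqs[first_idx]
  uniq_ids <- seqIds(dataset)[first_idx]
  derep <- setNames(uniq_ids[match(seqs, uniq_seqs)], seqIds(dataset))
  wts <- as.numeric(table(factor(derep, levels = uniq_ids)))

  cache <- new.env(parent = emptyenv())
  out <- vector("list", length(thresholds))
  names(out) <- .thrLabels(thresholds)
  res <- greedyCluster(uniq_ids, uniq_seqs, weights = wts,
                       threshold = thresholds[1L], cache = cache)
  # expand the first level's originMap from unique items to all records
  res@originMap <- setNames(unname(res@originMap[derep]), names(derep))
  validObject(res)
  out[[1L]] <- res
  for (i in seq_along(thresholds)[-1L])
    out[[i]] <- chainCluster(out[[i - 1L]], thresholds[i], cache = cache)
  out
}

#' Default clustering threshold ladder
#'
#' All 0.01 steps from 0.97 down to 0.75, endpoints included (23 levels).
#' 0.97 is the customary species-level proxy; below 0.75 nucleotide
#' alignments are generally considered too degraded to cluster on.
#'
#' @return Numeric vector of descending thresholds.
#' @export
defaultThresholds <- function() {
  round(seq(0.97, 0.75, by = -0.01), 2)
}

#' Build an OTU table from a clustering level
#'
#' Counts the dataset's records per (sample, OTU) cell through the level's
#' `originMap`. The grand total equals the dataset size.
#'
#' @param result A [ClusteringResult-class] whose `originMap` covers all
#'   records of `dataset`.
#' @param dataset The [AmpliconDataset-class] the clustering was derived from.
#' @return An [OTUTable-class] (samples x OTUs, sparse).
#' @export
buildOTUTable <- function(result, dataset) {
  stopifnot(is(result, "ClusteringResult"), is(dataset, "AmpliconDataset"))
  ids <- seqIds(dataset)
  missing <- setdiff(ids, names(result@originMap))
  .stop_if(length(missing) > 0L,
           "record(s) missing from originMap: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  .countTable(unname(result@originMap[ids]), dataset@sampleIds,
              dataset@samples, result@otuIds, result@threshold)
}

## Tabulate otu assignment x sample into a sparse OTUTable.
.countTable <- function(otu_of, sample_of, samples, otus, threshold) {
  i <- match(sample_of, samples)
  j <- match(otu_of, otus)
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                            x = rep(1, sum(keep)),
                            dims = c(length(samples), length(otus)),
                            dimnames = list(samples, otus))
  .newOTUTable(m, threshold)
}
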