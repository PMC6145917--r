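#' @include clustering.R
NULL

#' Mask an OTU table by a set of claimed sequences
#'
#' Recomputes the table's counts from the clustering level's `originMap` over
#' the dataset records *not* in `claimed`. OTU columns whose masked total
#' drops to zero are retained with zero counts, so OTU ids stay stable across
#' masking.
#'
#' @param table The [OTUTable-class] of the level.
#' @param result The [ClusteringResult-class] the table was built from.
#' @param claimed Character vector of original sequence ids already claimed
#'   by higher-threshold core OTUs (subset of the dataset's ids).
#' @param dataset The [AmpliconDataset-class].
#' @return A masked [OTUTable-class] with identical dimensions and labels.
#' @export
maskTable <- function(table, result, claimed, dataset) {
  stopifnot(is(table, "OTUTable"), is(result, "ClusteringResult"),
            is(dataset, "AmpliconDataset"))
  claimed <- as.character(claimed)
  .stop_if(!all(claimed %in% seqIds(dataset)),
           "claimed ids must be a subset of the dataset's sequence ids")
  if (length(claimed) == 0L) return(table)
  keep <- !(seqIds(dataset) %in% claimed)
  .countTable(unname(result@originMap[seqIds(dataset)[keep]]),
              dataset@sampleIds[keep],
              sampleIds(table), otuIds(table), table@threshold)
}

#' Detect core OTUs in a (masked) table at a prevalence threshold
#'
#' Returns, in table column order, the OTUs whose count is positive in at
#' least `ceiling(prevalence * n_samples)` samples. Presence is exact
#' (count > 0), not a relative-abundance floor; with the default
#' `prevalence = 1` an OTU must be present in every sample.
#'
#' @param maskedTable An [OTUTable-class] (typically after [maskTable()]).
#' @param prevalence Fraction in `(0, 1]`; default 1.
#' @return Character vector of core OTU ids (possibly empty).
#' @export
detectCoreAtLevel <- function(maskedTable, prevalence = 1) {
  stopifnot(is(maskedTable, "OTUTable"))
  stopifnot(prevalence > 0, prevalence <= 1)
  need <- ceiling(prevalence * nrow(maskedTable@counts))
  presence <- Matrix::colSums(maskedTable@counts > 0)
  otuIds(maskedTable)[presence >= need & presence > 0]
}

#' Run the dynamic phylogenetic core detection
#'
#' The central algorithm: the dataset is clustered once along the descending
#' threshold ladder ([ladderCluster()]); thresholds are then visited in
#' descending order, and at each level the level's OTU table is masked by the
#' union of all sequences claimed by cores found so far ([maskTable()]) before
#' core OTUs are designated ([detectCoreAtLevel()]). Each detected core claims
#' its masked membership (the level OTU's original sequences minus anything
#' already claimed), so core units are pairwise disjoint and no sequence
#' contributes below the threshold at which it was claimed.
#'
#' With `recluster = TRUE` the surviving (unclaimed) sequences are physically
#' re-clustered from scratch at each level instead of masking the
#' pre-computed chained tables; this is a literal reading of the iteration
#' cartoon and is provided for comparison. The default masking mode follows
#' the procedure text and is the tested reference behavior; the two are
#' nearly equivalent because of the chained ladder structure.
#'
#' @param dataset An [AmpliconDataset-class] with at least 2 samples.
#' @param thresholds Descending ladder; default [defaultThresholds()].
#' @param prevalence Fraction of samples an OTU must be present in; default 1
#'   (all samples).
#' @param recluster Logical; physically re-cluster unclaimed sequences at
#'   each level instead of masking the chained tables (default `FALSE`).
#' @return A [PhylogeneticCore-class]; its `levelTables` slot holds the
#'   per-level masked tables as evaluated.
#' @export
#' @examples
#' specs <- defaultLineageSpecs(nUniversal = 2, nSporadic = 2)
#' sim <- simulateDataset(specs, nSubjects = 4, depthPerSubject = 60,
#'                        seed = 1)
#' core <- runDynamicCore(sim$dataset, thresholds = c(0.97, 0.90, 0.85))
#' core
runDynamicCore <- function(dataset, thresholds = defaultThresholds(),
                           prevalence = 1, recluster = FALSE) {
  stopifnot(is(dataset, "AmpliconDataset"))
  .stop_if(length(dataset@samples) < 2L,
           "core detection needs at least 2 samples (a core over one sample ",
           "is vacuous)")
  .stop_if(any(diff(thresholds) >= 0),
           "thresholds must be strictly descending")

  ladder <- if (recluster) NULL else ladderCluster(dataset, thresholds)
  cache <- new.env(parent = emptyenv())
  claimed <- character(0)
  cores <- list()
  level_tables <- vector("list", length(thresholds))
  names(level_tables) <- .thrLabels(thresholds)

  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    if (recluster) {
      res <- .clusterSurvivors(dataset, claimed, t, cache)
      tbl <- .countTable(unname(res@originMap),
                         dataset@sampleIds[match(names(res@originMap),
                                                 seqIds(dataset))],
                         dataset@samples, res@otuIds, t)
    } else {
      res <- ladder[[i]]
      tbl <- maskTable(buildOTUTable(res, dataset), res, claimed, dataset)
    }
    level_tables[[i]] <- tbl
    core_ids <- detectCoreAtLevel(tbl, prevalence)
    for (otu in core_ids) {
      members <- names(res@originMap)[res@originMap == otu]
      members <- setdiff(members, claimed)
      if (length(members) == 0L) next
      counts <- table(factor(dataset@sampleIds[match(members,
                                                     seqIds(dataset))],
                             levels = dataset@samples))
      co <- new("CoreOTU",
                otuId = otu,
                detectionThreshold = t,
                representativeId = unname(res@representativeIds[otu]),
                representativeSeq = res@representativeSeqs[otu],
                maskedMemberIds = members,
                perSampleCounts = setNames(as.numeric(counts),
                                           names(counts)))
      cores[[length(cores) + 1L]] <- co
      claimed <- c(claimed, members)
    }
  }

  obj <- new("PhylogeneticCore",
             cores = cores,
             prevalence = prevalence,
             thresholdGrid = thresholds,
             sampleIds = dataset@samples,
             sampleDepths = sampleDepths(dataset),
             levelTables = level_tables,
             nSequences = length(dataset))
  validObject(obj)
  obj
}

## recluster-after-mask variant: de novo clustering of unclaimed records.
.clusterSurvivors <- function(dataset, claimed, threshold, cache = NULL) {
  keep <- !(seqIds(dataset) %in% claimed)
  ids <- seqIds(dataset)[keep]
  seqs <- as.character(dataset@sequences)[keep]
  if (length(ids) == 0L)
    return(greedyCluster(character(0), character(0), numeric(0),
                         threshold = threshold))
  first_idx <- which(!duplicated(seqs))
  uniq_seqs <- seqs[first_idx]
  uniq_ids <- ids[first_idx]
  derep <- setNames(uniq_ids[match(seqs, uniq_seqs)], ids)
  wts <- as.numeric(table(factor(derep, levels = uniq_ids)))
  res <- greedyCluster(uniq_ids, uniq_seqs, weights = wts,
                       threshold = threshold, cache = cache)
  res@originMap <- setNames(unname(res@originMap[derep]), names(derep))
  validObject(res)
  res
}

#' Tabulate detected cores as a data frame
#'
#' One row per core OTU: id, detection threshold, representative id, number
#' of claimed sequences, and the number of samples it is present in.
#'
#' @param core A [PhylogeneticCore-class].
#' @return A `data.frame`.
#' @export
coresAsDataFrame <- function(core) {
  stopifnot(is(core, "PhylogeneticCore"))
  if (length(core@cores) == 0L)
    return(data.frame(otuId = character(0), threshold = numeric(0),
                      representativeId = character(0), nSequences = integer(0),
                      nSamplesPresent = integer(0)))
  data.frame(
    otuId = vapply(core@cores, function(x) x@otuId, character(1)),
    threshold = vapply(core@cores, function(x) x@detectionThreshold,
                       numeric(1)),
    representativeId = vapply(core@cores, function(x) x@representativeId,
                              character(1)),
    nSequences = vapply(core@cores, function(x)
      length(x@maskedMemberIds), integer(1)),
    nSamplesPresent = vapply(core@cores, function(x)
      sum(x@perSampleCounts > 0), integer(1)),
    row.names = NULL
  )
}
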