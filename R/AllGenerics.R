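#' @include AllClasses.R
NULL

#' Accessors for phylocore classes
#'
#' @param x A phylocore object.
#' @param ... Unused.
#'
#' @return `seqIds`: character vector of sequence ids. `sampleIds`: sample
#'   attribution (per read for an `AmpliconDataset`, the row names for an
#'   `OTUTable`). `sampleNames`: the ordered unique sample ids.
#'   `sequences`: a [Biostrings::DNAStringSet]. `sampleDepths`: named per-
#'   sample read counts. `otuIds`: OTU ids. `otuCounts`: the counts matrix.
#'   `clusterThreshold`: the identity threshold. `coreOTUs`: list of
#'   [CoreOTU-class]. `coreCount`: number of detected cores.
#'
#' @name accessors
#' @aliases seqIds sampleIds sampleNames sequences sampleDepths otuIds
#'   otuCounts clusterThreshold coreOTUs coreCount originMap
#'   representativeSeqs
NULL

#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("sampleDepths", function(x) standardGeneric("sampleDepths"))

#' @rdname accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("clusterThreshold", function(x) standardGeneric("clusterThreshold"))

#' @rdname accessors
#' @export
setGeneric("coreOTUs", function(x) standardGeneric("coreOTUs"))

#' @rdname accessors
#' @export
setGeneric("coreCount", function(x) standardGeneric("coreCount"))

#' @rdname accessors
#' @export
setGeneric("originMap", function(x) standardGeneric("originMap"))

#' @rdname accessors
#' @export
setGeneric("representativeSeqs", function(x) standardGeneric("representativeSeqs"))

## ---- AmpliconDataset ----

#' @rdname accessors
setMethod("seqIds", "AmpliconDataset", function(x) names(x@sequences))

#' @rdname accessors
setMethod("sampleIds", "AmpliconDataset", function(x) x@sampleIds)

#' @rdname accessors
setMethod("sampleNames", "AmpliconDataset", function(x) x@samples)

#' @rdname accessors
setMethod("sequences", "AmpliconDataset", function(x) x@sequences)

#' @rdname accessors
setMethod("sampleDepths", "AmpliconDataset", function(x) {
  d <- table(factor(x@sampleIds, levels = x@samples))
  setNames(as.numeric(d), names(d))
})

setMethod("length", "AmpliconDataset", function(x) length(x@sequences))

setMethod("show", "AmpliconDataset", function(object) {
  d <- sampleDepths(object)
  cat("AmpliconDataset with", length(object), "sequences across",
      length(object@samples), "samples\n")
  if (length(d))
    cat("  per-sample depth: min", min(d), "/ max", max(d), "\n")
  if (length(object))
    cat("  read length: ",
        paste(range(Biostrings::width(object@sequences)), collapse = "-"),
        " nt\n", sep = "")
})

## ---- OTUTable ----

#' @rdname accessors
setMethod("sampleIds", "OTUTable", function(x) rownames(x@counts))

#' @rdname accessors
setMethod("otuIds", "OTUTable", function(x) colnames(x@counts))

#' @rdname accessors
setMethod("otuCounts", "OTUTable", function(x) x@counts)

#' @rdname accessors
setMethod("clusterThreshold", "OTUTable", function(x) x@threshold)

#' @rdname accessors
setMethod("sampleDepths", "OTUTable", function(x) {
  setNames(as.numeric(Matrix::rowSums(x@counts)), rownames(x@counts))
})

setMethod("show", "OTUTable", function(object) {
  cat("OTUTable at threshold ", format(object@threshold), ": ",
      nrow(object@counts), " samples x ", ncol(object@counts), " OTUs, ",
      sum(object@counts), " total counts\n", sep = "")
})

## ---- ClusteringResult ----

#' @rdname accessors
setMethod("otuIds", "ClusteringResult", function(x) x@otuIds)

#' @rdname accessors
setMethod("clusterThreshold", "ClusteringResult", function(x) x@threshold)

#' @rdname accessors
setMethod("originMap", "ClusteringResult", function(x) x@originMap)

#' @rdname accessors
setMethod("representativeSeqs", "ClusteringResult",
          function(x) x@representativeSeqs)

setMethod("length", "ClusteringResult", function(x) length(x@otuIds))

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult at threshold ", format(object@threshold), ": ",
      length(object@otuIds), " OTUs over ", length(object@originMap),
      " original sequences\n", sep = "")
})

## ---- CoreOTU / PhylogeneticCore ----

#' @rdname accessors
setMethod("otuIds", "CoreOTU", function(x) x@otuId)

#' @rdname accessors
setMethod("clusterThreshold", "CoreOTU", function(x) x@detectionThreshold)

setMethod("show", "CoreOTU", function(object) {
  cat("CoreOTU ", object@otuId, " (threshold ",
      format(object@detectionThreshold), "): ",
      length(object@maskedMemberIds), " sequences over ",
      sum(object@perSampleCounts > 0), " samples\n", sep = "")
})

#' @rdname accessors
setMethod("coreOTUs", "PhylogeneticCore", function(x) x@cores)

#' @rdname accessors
setMethod("coreCount", "PhylogeneticCore", function(x) length(x@cores))

#' @rdname accessors
setMethod("sampleNames", "PhylogeneticCore", function(x) x@sampleIds)

#' @rdname accessors
setMethod("sampleDepths", "PhylogeneticCore", function(x) x@sampleDepths)

setMethod("length", "PhylogeneticCore", function(x) length(x@cores))

setMethod("show", "PhylogeneticCore", function(object) {
  cat("PhylogeneticCore: ", length(object@cores), " core OTUs over ",
      length(object@sampleIds), " samples (prevalence ",
      format(object@prevalence), ")\n", sep = "")
  if (length(object@cores)) {
    thr <- vapply(object@cores, function(co) co@detectionThreshold, numeric(1))
    tab <- table(factor(.thrLabels(thr), levels = unique(.thrLabels(thr))))
    cat("  cores per threshold: ",
        paste0(names(tab), ":", as.integer(tab), collapse = ", "), "\n",
        sep = "")
    claimed <- sum(vapply(object@cores, function(co)
      length(co@maskedMemberIds), numeric(1)))
    cat("  sequences claimed: ", claimed, " / ", object@nSequences, "\n",
        sep = "")
  }
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult at threshold ", format(object@threshold), ": ",
      "observed ", object@observedCoreCount, " core OTUs, p = ",
      format(object@pValue), " (", object@nPermutations,
      " permutations)\n", sep = "")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth: ", length(object@recordLineage), " reads, ",
      length(object@lineages), " lineages (",
      sum(vapply(object@lineages, `[[`, logical(1), "universal")),
      " universal)\n", sep = "")
})

setMethod("show", "LineageSpec", function(object) {
  cat("LineageSpec ", object@lineageId, ": ",
      if (object@universal) "universal" else
        paste0("sporadic (occupancy ", format(object@occupancy), ")"),
      ", diversity ", format(object@intraDivergence), "\n", sep = "")
})
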