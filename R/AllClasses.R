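#' @include phylocore-package.R
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' AmpliconDataset: multi-subject amplicon sequence collection
#'
#' Holds demultiplexed amplicon reads with their sample (subject) attribution.
#' Sequence order is the input order and is preserved by all operations.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by unique sequence ids.
#' @slot sampleIds Character vector parallel to `sequences`; the sample each
#'   read belongs to.
#' @slot samples Ordered character vector of unique sample ids (first-seen
#'   order).
#'
#' @seealso [readFastaWithSamples()], [subsampleCommonDepth()],
#'   [simulateDataset()]
#' @exportClass AmpliconDataset
setClass("AmpliconDataset",
  representation(
    sequences = "DNAStringSet",
    sampleIds = "character",
    samples = "character"
  )
)

setValidity("AmpliconDataset", function(object) {
  msg <- character(0)
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must carry non-empty ids")
  else if (anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique within a dataset")
  if (length(object@sampleIds) != length(object@sequences))
    msg <- c(msg, "sampleIds must be parallel to sequences")
  if (any(object@sampleIds == "" | is.na(object@sampleIds)))
    msg <- c(msg, "sample ids must be non-empty")
  if (!all(object@sampleIds %in% object@samples))
    msg <- c(msg, "every record's sample id must be listed in samples")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
    msg <- c(msg, "residues must be non-empty")
  if (length(msg)) msg else TRUE
})

#' OTUTable: subjects x OTUs count matrix at one clustering threshold
#'
#' @slot counts Sparse numeric matrix (samples in rows, OTUs in columns) of
#'   non-negative integer counts, with dimnames.
#' @slot threshold Clustering identity threshold in `[0, 1]` the table was
#'   built at.
#'
#' @seealso [buildOTUTable()], [maskTable()], [writeOTUTable()]
#' @exportClass OTUTable
setClass("OTUTable",
  representation(
    counts = "dgCMatrix",
    threshold = "numeric"
  )
)

setValidity("OTUTable", function(object) {
  msg <- character(0)
  cn <- colnames(object@counts)
  rn <- rownames(object@counts)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "sample ids must be present and unique")
  if (ncol(object@counts) > 0 && (is.null(cn) || anyDuplicated(cn)))
    msg <- c(msg, "OTU ids must be present and unique")
  if (length(object@counts@x) && any(object@counts@x < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@counts@x) && any(object@counts@x != round(object@counts@x)))
    msg <- c(msg, "counts must be integers")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ClusteringResult: OTUs at one identity threshold
#'
#' Result of greedy centroid clustering at a single threshold, with a total
#' membership map from original sequence ids to OTU ids (`originMap`). At
#' chained levels the clustered items are the previous level's representative
#' sequences while `originMap` remains total over the original input.
#'
#' @slot threshold Identity threshold of this level.
#' @slot otuIds OTU ids in creation order (`T<threshold*100>_<k>`).
#' @slot representativeIds Named character (OTU id -> representative seq id).
#' @slot representativeSeqs [Biostrings::DNAStringSet] of representative
#'   sequences named by OTU id.
#' @slot members Named list (OTU id -> character vector of item ids clustered
#'   at this level).
#' @slot originMap Named character: original sequence id -> OTU id.
#'
#' @seealso [greedyCluster()], [chainCluster()], [ladderCluster()]
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(
    threshold = "numeric",
    otuIds = "character",
    representativeIds = "character",
    representativeSeqs = "DNAStringSet",
    members = "list",
    originMap = "character"
  )
)

setValidity("ClusteringResult", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@otuIds))
    msg <- c(msg, "OTU ids must be unique")
  if (!identical(sort(names(object@members)), sort(object@otuIds)))
    msg <- c(msg, "members must be named by the OTU ids")
  if (length(object@otuIds)) {
    if (!all(object@originMap %in% object@otuIds))
      msg <- c(msg, "originMap must be surjective onto the OTU ids")
    reps_in <- vapply(object@otuIds, function(o)
      object@representativeIds[[o]] %in% object@members[[o]], logical(1))
    if (!all(reps_in))
      msg <- c(msg, "each representative must be a member of its OTU")
    if (any(vapply(object@members, length, integer(1)) == 0L))
      msg <- c(msg, "member sets must be non-empty")
    all_members <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_members))
      msg <- c(msg, "member sets of distinct OTUs must be disjoint")
  } else if (length(object@originMap)) {
    msg <- c(msg, "originMap must be empty when there are no OTUs")
  }
  if (length(msg)) msg else TRUE
})

#' CoreOTU: one detected core unit
#'
#' A core OTU is an OTU present in at least the configured prevalence fraction
#' of subjects (default all of them), designated at the highest ladder
#' threshold at which this holds after masking sequences already claimed by
#' higher-threshold cores. Its sequence set (`maskedMemberIds`) therefore
#' excludes any read claimed at a higher threshold.
#'
#' @slot otuId OTU id at the detection level.
#' @slot detectionThreshold Ladder threshold the core was designated at.
#' @slot representativeId Sequence id of the level representative.
#' @slot representativeSeq Length-1 [Biostrings::DNAStringSet].
#' @slot maskedMemberIds Original sequence ids claimed by this core.
#' @slot perSampleCounts Named numeric: per-sample count over masked members.
#'
#' @exportClass CoreOTU
setClass("CoreOTU",
  representation(
    otuId = "character",
    detectionThreshold = "numeric",
    representativeId = "character",
    representativeSeq = "DNAStringSet",
    maskedMemberIds = "character",
    perSampleCounts = "numeric"
  )
)

setValidity("CoreOTU", function(object) {
  msg <- character(0)
  if (length(object@maskedMemberIds) == 0L)
    msg <- c(msg, "a core OTU must claim at least one sequence")
  if (sum(object@perSampleCounts) != length(object@maskedMemberIds))
    msg <- c(msg, "per-sample counts must total the masked membership")
  if (length(msg)) msg else TRUE
})

#' PhylogeneticCore: the full dynamic-core result
#'
#' Ordered collection of [CoreOTU-class] units detected along the threshold
#' ladder (descending threshold, then OTU creation order), together with the
#' per-level masked OTU tables used for detection. Masked member sets of
#' distinct cores are pairwise disjoint.
#'
#' @slot cores List of [CoreOTU-class].
#' @slot prevalence Prevalence fraction used for detection (default 1.0).
#' @slot thresholdGrid The descending threshold ladder.
#' @slot sampleIds Sample ids of the analyzed dataset.
#' @slot sampleDepths Named numeric per-sample sequence depths
#'   (post-subsampling).
#' @slot levelTables Named list (threshold label -> masked [OTUTable-class])
#'   as evaluated during detection. May be empty for deserialized objects.
#' @slot nSequences Number of sequences in the analyzed dataset.
#'
#' @seealso [runDynamicCore()], [pooledCoreFrequency()]
#' @exportClass PhylogeneticCore
setClass("PhylogeneticCore",
  representation(
    cores = "list",
    prevalence = "numeric",
    thresholdGrid = "numeric",
    sampleIds = "character",
    sampleDepths = "numeric",
    levelTables = "list",
    nSequences = "integer"
  )
)

setValidity("PhylogeneticCore", function(object) {
  msg <- character(0)
  if (!all(vapply(object@cores, is, logical(1), "CoreOTU")))
    msg <- c(msg, "cores must be CoreOTU objects")
  claimed <- unlist(lapply(object@cores, function(co) co@maskedMemberIds),
                    use.names = FALSE)
  if (anyDuplicated(claimed))
    msg <- c(msg, "masked member sets of cores must be pairwise disjoint")
  if (length(claimed) > object@nSequences)
    msg <- c(msg, "cores cannot claim more sequences than the dataset holds")
  thr <- vapply(object@cores, function(co) co@detectionThreshold, numeric(1))
  if (length(thr) && !all(vapply(thr, function(t)
      any(abs(t - object@thresholdGrid) < 1e-9), logical(1))))
    msg <- c(msg, "every detection threshold must lie on the threshold grid")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: core-count significance at one threshold
#'
#' @slot threshold Clustering threshold of the tested table.
#' @slot observedCoreCount Number of OTUs meeting the prevalence rule in the
#'   observed table.
#' @slot nullCounts Integer vector of core counts over shuffled tables.
#' @slot pValue Add-one empirical p-value, `(1 + #null >= observed) / (1 + n)`.
#' @slot nPermutations Number of shuffled tables.
#' @slot seed Seed used for shuffling.
#'
#' @seealso [permutationCoreTest()]
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    threshold = "numeric",
    observedCoreCount = "integer",
    nullCounts = "integer",
    pValue = "numeric",
    nPermutations = "integer",
    seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- character(0)
  if (length(object@nullCounts) != object@nPermutations)
    msg <- c(msg, "nullCounts length must equal nPermutations")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimulationTruth: ground truth of a simulated community
#'
#' @slot recordLineage Named character: read id -> lineage id.
#' @slot lineages List per lineage: `ancestor`, `variants` (DNAStringSet),
#'   `intraDivergence`, `universal`, `occupancy`.
#' @slot composition Numeric matrix subjects x lineages of read counts.
#' @slot specs The list of [LineageSpec-class] used.
#' @slot seed Simulation seed.
#'
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(
    recordLineage = "character",
    lineages = "list",
    composition = "matrix",
    specs = "list",
    seed = "integer"
  )
)

#' LineageSpec: specification of one simulated lineage
#'
#' `intraDivergence` controls the lineage's sequence diversity: every variant
#' (strain) differs from the lineage ancestor at exactly
#' `round(intraDivergence / 2 * ancestorLength)` positions, so the maximum
#' pairwise divergence between strains (the lineage's diameter) is
#' approximately `intraDivergence`.
#'
#' @slot lineageId Unique lineage id.
#' @slot ancestorLength Ancestor sequence length in nt (default 250, typical
#'   V4 read length).
#' @slot intraDivergence Maximum pairwise divergence among variants, in
#'   `[0, 0.2]`.
#' @slot nVariants Number of distinct strains; `NA` means one per subject
#'   (resolved by [simulateDataset()]).
#' @slot universal Logical; planted in every subject vs sporadic.
#' @slot occupancy Per-subject inclusion probability for sporadic lineages.
#' @slot baseAbundance Relative abundance weight.
#' @slot abundanceDispersion Log-scale sd of the per-subject abundance jitter.
#'
#' @seealso [lineageSpec()], [simulateDataset()]
#' @exportClass LineageSpec
setClass("LineageSpec",
  representation(
    lineageId = "character",
    ancestorLength = "integer",
    intraDivergence = "numeric",
    nVariants = "integer",
    universal = "logical",
    occupancy = "numeric",
    baseAbundance = "numeric",
    abundanceDispersion = "numeric"
  )
)

setValidity("LineageSpec", function(object) {
  msg <- character(0)
  if (object@intraDivergence < 0 || object@intraDivergence > 0.2)
    msg <- c(msg, "intraDivergence must lie in [0, 0.2]")
  if (!object@universal &&
      (object@occupancy <= 0 || object@occupancy >= 1))
    msg <- c(msg, "occupancy must lie in (0, 1) for sporadic lineages")
  if (object@ancestorLength < 1L)
    msg <- c(msg, "ancestorLength must be positive")
  if (object@baseAbundance < 0)
    msg <- c(msg, "baseAbundance must be non-negative")
  if (length(msg)) msg else TRUE
})
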