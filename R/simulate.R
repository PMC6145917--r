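#' @include refmatch.R
NULL

#' Construct a lineage specification
#'
#' See [LineageSpec-class] for the meaning of the fields. Defaults describe a
#' 250 nt V4-like amplicon lineage with moderate inter-subject abundance
#' variation.
#'
#' @param lineageId Unique id.
#' @param ancestorLength Ancestor length in nt (default 250).
#' @param intraDivergence Maximum pairwise divergence among the lineage's
#'   strains (default 0; all strains identical).
#' @param nVariants Number of strains; `NA` (default) resolves to one strain
#'   per subject in [simulateDataset()].
#' @param universal Planted in every subject (default `TRUE`)?
#' @param occupancy Per-subject inclusion probability when sporadic
#'   (default 0.5).
#' @param baseAbundance Relative abundance weight (default 1).
#' @param abundanceDispersion Log-scale sd of per-subject abundance jitter
#'   (default 1, a log-normal spread typical of gut taxa).
#' @return A [LineageSpec-class].
#' @export
lineageSpec <- function(lineageId, ancestorLength = 250L,
                        intraDivergence = 0, nVariants = NA_integer_,
                        universal = TRUE, occupancy = 0.5,
                        baseAbundance = 1, abundanceDispersion = 1) {
  new("LineageSpec",
      lineageId = as.character(lineageId),
      ancestorLength = as.integer(ancestorLength),
      intraDivergence = intraDivergence,
      nVariants = as.integer(nVariants),
      universal = universal,
      occupancy = occupancy,
      baseAbundance = baseAbundance,
      abundanceDispersion = abundanceDispersion)
}

#' Default lineage panel for simulation studies
#'
#' A panel of `nUniversal` universal (planted-core) lineages and `nSporadic`
#' sporadic lineages. Intra-lineage divergences cycle deterministically
#' through `intraLevels`, so the panel always spans phylogenetically shallow
#' (single 0.97 cluster) and deep (mid-ladder) core structure.
#'
#' @param nUniversal Number of universal lineages (default 5).
#' @param nSporadic Number of sporadic lineages (default 15).
#' @param intraLevels Divergence levels cycled over lineages (default
#'   `c(0, 0.02, 0.06, 0.10)`).
#' @param occupancy Occupancy probability of sporadic lineages (default 0.5).
#' @param ancestorLength Ancestor length (default 250).
#' @return List of [LineageSpec-class].
#' @export
defaultLineageSpecs <- function(nUniversal = 5, nSporadic = 15,
                                intraLevels = c(0, 0.02, 0.06, 0.10),
                                occupancy = 0.5, ancestorLength = 250L) {
  specs <- list()
  iu <- rep_len(intraLevels, nUniversal)
  for (k in seq_len(nUniversal))
    specs[[length(specs) + 1L]] <-
      lineageSpec(sprintf("U%02d", k), ancestorLength = ancestorLength,
                  intraDivergence = iu[k], universal = TRUE)
  is <- rep_len(intraLevels, nSporadic)
  for (k in seq_len(nSporadic))
    specs[[length(specs) + 1L]] <-
      lineageSpec(sprintf("P%02d", k), ancestorLength = ancestorLength,
                  intraDivergence = is[k], universal = FALSE,
                  occupancy = occupancy)
  specs
}

## Draw one random DNA sequence using the current RNG stream.
.randomDNAseq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## Substitute exactly k positions of a sequence (uniform sites, uniform
## different base) using the current RNG stream.
.substituteExact <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sites <- sample(length(chars), k)
  for (s in sites)
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
  paste(chars, collapse = "")
}

#' Simulate lineage ancestor and strain sequences
#'
#' Random ancestors are drawn until all pairwise ancestor identities are at
#' most `1 - minInterDivergence` (separability); strains are then generated
#' from each ancestor by substituting exactly
#' `round(intraDivergence / 2 * length)` uniformly chosen positions, so the
#' maximum pairwise divergence among a lineage's strains is approximately
#' `intraDivergence`. Deterministic given `seed`.
#'
#' @param specs List of [LineageSpec-class]; `nVariants` must be resolved
#'   (`NA` entries default to 4 when called directly).
#' @param minInterDivergence Minimum divergence between lineage ancestors
#'   (default 0.25). A warning is issued if it does not exceed twice the
#'   largest intra-lineage divergence (separability).
#' @param seed Integer seed.
#' @param maxAttempts Resampling budget per ancestor before giving up
#'   (default 200).
#' @return Named list per lineage: `ancestor` (character), `variants`
#'   (named [Biostrings::DNAStringSet]), `intraDivergence`, `universal`,
#'   `occupancy`.
#' @export
simulateLineages <- function(specs, minInterDivergence = 0.25, seed,
                             maxAttempts = 200) {
  stopifnot(all(vapply(specs, is, logical(1), "LineageSpec")))
  .stop_if(missing(seed), "simulateLineages requires a seed")
  ids <- vapply(specs, function(s) s@lineageId, character(1))
  .stop_if(anyDuplicated(ids) > 0L, "duplicate lineage id: ",
           ids[anyDuplicated(ids)])
  max_intra <- max(vapply(specs, function(s) s@intraDivergence, numeric(1)))
  if (minInterDivergence <= 2 * max_intra)
    warning("minInterDivergence (", minInterDivergence,
            ") does not exceed twice the largest intraDivergence (",
            max_intra, "); lineages may not be separable", call. = FALSE)

  .withSeed(seed, {
    ancestors <- character(0)
    for (s in specs) {
      ok <- FALSE
      for (att in seq_len(maxAttempts)) {
        cand <- .randomDNAseq(s@ancestorLength)
        if (length(ancestors) == 0L ||
            all(.identityMany(cand, ancestors) <= 1 - minInterDivergence)) {
          ancestors <- c(ancestors, cand)
          ok <- TRUE
          break
        }
      }
      .stop_if(!ok, "could not satisfy ancestor separability for lineage ",
               s@lineageId, " within ", maxAttempts, " attempts")
    }
    names(ancestors) <- ids

    out <- lapply(seq_along(specs), function(i) {
      s <- specs[[i]]
      nv <- if (is.na(s@nVariants)) 4L else s@nVariants
      k <- as.integer(round(s@intraDivergence / 2 * s@ancestorLength))
      vars <- vapply(seq_len(nv), function(v)
        .substituteExact(ancestors[[i]], k), character(1))
      dss <- Biostrings::DNAStringSet(vars)
      names(dss) <- sprintf("%s.v%02d", s@lineageId, seq_len(nv))
      list(ancestor = ancestors[[i]], variants = dss,
           intraDivergence = s@intraDivergence,
           universal = s@universal, occupancy = s@occupancy)
    })
    names(out) <- ids
    out
  })
}

#' Simulate a multi-subject amplicon dataset with known ground truth
#'
#' Emulates the community structure the dynamic-core analysis assumes:
#' lineages of controlled phylogenetic depth, some planted as universally
#' present and some sporadic, log-normal abundance variation across subjects,
#' and a fixed per-subject sequencing depth. Each subject carries its own
#' strain of each lineage (strains assigned round-robin from the lineage's
#' variant pool; with the default `nVariants = NA` the pool has one strain
#' per subject, so strains are subject-private). Universal lineages are
#' guaranteed at least one read per subject (forced allocation from the
#' subject's largest lineage), so "universal" means detectable-universal at
#' the simulated depth.
#'
#' @param specs List of [LineageSpec-class], e.g. [defaultLineageSpecs()].
#' @param nSubjects Number of subjects (default 10).
#' @param depthPerSubject Reads per subject (default 500).
#' @param minInterDivergence Passed to [simulateLineages()] (default 0.25).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list: `dataset` (an [AmpliconDataset-class]) and `truth`
#'   (a [SimulationTruth-class]).
#' @export
#' @examples
#' sim <- simulateDataset(defaultLineageSpecs(2, 2), nSubjects = 3,
#'                        depthPerSubject = 50, seed = 7)
#' sim$dataset
simulateDataset <- function(specs, nSubjects = 10, depthPerSubject = 500,
                            minInterDivergence = 0.25, seed) {
  stopifnot(all(vapply(specs, is, logical(1), "LineageSpec")))
  .stop_if(missing(seed), "simulateDataset requires a seed")
  stopifnot(nSubjects >= 2, depthPerSubject >= 1)
  .stop_if(all(vapply(specs, function(s) s@baseAbundance, numeric(1)) == 0),
           "degenerate specs: all abundance weights are zero")

  # resolve strain pools: default one private strain per subject
  specs <- lapply(specs, function(s) {
    if (is.na(s@nVariants)) s@nVariants <- as.integer(nSubjects)
    s
  })
  lineages <- simulateLineages(specs, minInterDivergence,
                               seed = deriveSeed(seed, "lineages"))
  ids <- names(lineages)
  universal <- vapply(lineages, `[[`, logical(1), "universal")

  subjects <- sprintf("S%02d", seq_len(nSubjects))
  rec_ids <- character(0)
  rec_seqs <- character(0)
  rec_samples <- character(0)
  rec_lineage <- character(0)
  composition <- matrix(0, nrow = nSubjects, ncol = length(ids),
                        dimnames = list(subjects, ids))

  .withSeed(deriveSeed(seed, "composition"), {
    for (si in seq_len(nSubjects)) {
      include <- universal |
        vapply(lineages, function(l)
          !l$universal && stats::runif(1) < l$occupancy, logical(1))
      w <- vapply(seq_along(specs), function(i) {
        if (!include[i]) return(0)
        specs[[i]]@baseAbundance *
          stats::rlnorm(1, 0, specs[[i]]@abundanceDispersion)
      }, numeric(1))
      .stop_if(sum(w) == 0, "no lineage included for subject ",
               subjects[si])
      counts <- as.integer(rmultinom(1, depthPerSubject, w))
      # universal lineages must be detectable at this depth
      zero_u <- which(universal & counts == 0L)
      for (z in zero_u) {
        donor <- which.max(counts)
        counts[donor] <- counts[donor] - 1L
        counts[z] <- 1L
      }
      for (i in seq_along(specs)) {
        if (counts[i] == 0L) next
        pool <- lineages[[i]]$variants
        strain <- as.character(pool[[((si - 1L) %% length(pool)) + 1L]])
        n_new <- counts[i]
        idx <- length(rec_ids) + seq_len(n_new)
        rec_ids <- c(rec_ids, sprintf("%s_%06d", subjects[si],
                                       length(rec_ids[rec_samples ==
                                                      subjects[si]]) +
                                         seq_len(n_new)))
        rec_seqs <- c(rec_seqs, rep(strain, n_new))
        rec_samples <- c(rec_samples, rep(subjects[si], n_new))
        rec_lineage <- c(rec_lineage, rep(ids[i], n_new))
        composition[si, i] <- counts[i]
      }
    }
  })

  dataset <- .newDataset(rec_ids, rec_seqs, rec_samples)
  truth <- new("SimulationTruth",
               recordLineage = setNames(rec_lineage, rec_ids),
               lineages = lineages,
               composition = composition,
               specs = specs,
               seed = as.integer(seed))
  list(dataset = dataset, truth = truth)
}

#' Compare detected cores to the simulation ground truth
#'
#' Maps every detected core OTU to the lineage contributing the majority of
#' its claimed sequences, and scores the recovered lineage set against the
#' planted universal lineages: precision = fraction of recovered lineages
#' that are universal, recall = fraction of universal lineages recovered.
#' Also reports per-core purity (fraction of claimed reads from the majority
#' lineage).
#'
#' @param core A [PhylogeneticCore-class].
#' @param truth A [SimulationTruth-class] from [simulateDataset()].
#' @return A list: `recovered` (character), `universal` (character),
#'   `precision`, `recall`, `perCore` (data frame with `otuId`, `threshold`,
#'   `lineage`, `purity`).
#' @export
evaluateRecovery <- function(core, truth) {
  stopifnot(is(core, "PhylogeneticCore"), is(truth, "SimulationTruth"))
  universal <- names(truth@lineages)[vapply(truth@lineages, `[[`,
                                            logical(1), "universal")]
  per_core <- lapply(core@cores, function(co) {
    lin <- truth@recordLineage[co@maskedMemberIds]
    tab <- sort(table(lin), decreasing = TRUE)
    data.frame(otuId = co@otuId, threshold = co@detectionThreshold,
               lineage = names(tab)[1L],
               purity = as.integer(tab[1L]) / length(lin),
               row.names = NULL)
  })
  per_core <- if (length(per_core))
    do.call(rbind, c(per_core, list(make.row.names = FALSE)))
  else data.frame(otuId = character(0), threshold = numeric(0),
                  lineage = character(0), purity = numeric(0))
  recovered <- unique(per_core$lineage)
  precision <- if (length(recovered))
    length(intersect(recovered, universal)) / length(recovered) else NA_real_
  recall <- if (length(universal))
    length(intersect(recovered, universal)) / length(universal) else NA_real_
  list(recovered = recovered, universal = universal,
       precision = precision, recall = recall, perCore = per_core)
}
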