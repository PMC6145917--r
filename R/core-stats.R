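#' @include permutation.R
NULL

#' Pooled core frequency across samples
#'
#' For each sample `s`, the pooled core frequency is the percentage of that
#' sample's sequences claimed by any core OTU:
#' `f_s = 100 * sum_cores(masked count in s) / depth_s`. Because core masked
#' memberships are disjoint, `f_s` is additive over cores and bounded by 100.
#' Returns the mean, sd, minimum and maximum of `f_s` over samples (the
#' "Frequency" and "Range" summaries of a phylogenetic core).
#'
#' @param core A [PhylogeneticCore-class].
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"` (n).
#' @return Named numeric: `mean`, `sd`, `min`, `max`, in percent.
#' @export
#' @examples
#' ## three samples covering 50%, 60%, 70% of reads give 60 +/- 10, range
#' ## 50-70 (see the package tests for a hand-built fixture)
pooledCoreFrequency <- function(core, sdType = c("sample", "population")) {
  stopifnot(is(core, "PhylogeneticCore"))
  sdType <- match.arg(sdType)
  depths <- core@sampleDepths
  .stop_if(any(depths == 0), "sample with zero depth")
  n <- length(core@sampleIds)
  f <- setNames(numeric(n), core@sampleIds)
  for (co in core@cores)
    f <- f + co@perSampleCounts[core@sampleIds]
  f <- 100 * f / depths[core@sampleIds]
  s <- if (n < 2) 0 else sd(f)
  if (sdType == "population") s <- s * sqrt((n - 1) / n)
  if (length(core@cores) == 0L) f[] <- 0
  c(mean = mean(f), sd = s, min = min(f), max = max(f))
}

#' Per-core abundance and stability statistics
#'
#' For each core OTU: the mean relative abundance across samples (relative to
#' post-subsampling sample depth), the coefficient of variation (sd/mean of
#' the per-sample relative abundances), and the abundance-rank percentile of
#' the core within the empirical cumulative distribution of mean relative
#' abundances of *all* OTUs at its detection level (1 = the most abundant OTU
#' of its level).
#'
#' @param core A [PhylogeneticCore-class] with populated `levelTables`.
#' @param tables Optional named list of per-level masked [OTUTable-class];
#'   defaults to the tables stored in `core`.
#' @return A `data.frame` with one row per core OTU: `otuId`, `threshold`,
#'   `meanRelAbundance`, `cv`, `percentile`.
#' @export
perCoreAbundanceStats <- function(core, tables = core@levelTables) {
  stopifnot(is(core, "PhylogeneticCore"))
  .stop_if(length(tables) == 0L, "per-level masked tables are required")
  if (length(core@cores) == 0L)
    return(data.frame(otuId = character(0), threshold = numeric(0),
                      meanRelAbundance = numeric(0), cv = numeric(0),
                      percentile = numeric(0)))
  depths <- core@sampleDepths[core@sampleIds]
  rows <- lapply(core@cores, function(co) {
    lv <- format(co@detectionThreshold)
    tbl <- tables[[lv]]
    .stop_if(is.null(tbl), "no level table for threshold ", lv)
    rel <- co@perSampleCounts[core@sampleIds] / depths
    mu <- mean(rel)
    cv <- if (mu == 0) NA_real_ else sd(rel) / mu
    # mean relative abundance of every OTU at this level, masked view
    relmat <- tbl@counts / depths
    level_means <- Matrix::colSums(relmat) / length(depths)
    # evaluate at the core's own column mean so the comparison is exact
    pct <- abundanceECDF(as.numeric(level_means))(level_means[[co@otuId]])
    data.frame(otuId = co@otuId, threshold = co@detectionThreshold,
               meanRelAbundance = mu, cv = cv, percentile = pct,
               row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF of a non-empty numeric vector; `f(max(values))` is 1.
#'
#' @param values Non-empty numeric vector.
#' @return A step function, as from [stats::ecdf()].
#' @export
#' @examples
#' abundanceECDF(c(1, 2, 3))(2)  # 2/3
abundanceECDF <- function(values) {
  .stop_if(length(values) == 0L, "ECDF of an empty vector is undefined")
  .stop_if(anyNA(values), "ECDF input must not contain NA")
  stats::ecdf(values)
}

#' Summarize a phylogenetic core
#'
#' Collects the headline numbers of a detected core: pooled frequency
#' mean/sd and range across samples, the number of core OTUs per threshold,
#' and the per-core abundance statistics.
#'
#' @param core A [PhylogeneticCore-class].
#' @param nPermutations,seed If both supplied, per-level permutation p-values
#'   are included.
#' @return A list with elements `frequency` (mean, sd, min, max),
#'   `perLevelCounts` (named integer), `perCore` (data frame), and optionally
#'   `pValues`.
#' @export
coreSummary <- function(core, nPermutations = NULL, seed = NULL) {
  stopifnot(is(core, "PhylogeneticCore"))
  thr <- vapply(core@cores, function(co) co@detectionThreshold, numeric(1))
  lv <- factor(.thrLabels(thr), levels = .thrLabels(core@thresholdGrid))
  counts <- table(lv)
  out <- list(
    frequency = pooledCoreFrequency(core),
    perLevelCounts = setNames(as.integer(counts), names(counts)),
    perCore = if (length(core@levelTables) && length(core@cores))
      perCoreAbundanceStats(core) else NULL
  )
  if (!is.null(nPermutations) && !is.null(seed) &&
      length(core@levelTables)) {
    pr <- permutationTestAllLevels(core, nPermutations, seed)
    out$pValues <- vapply(pr, function(x) x@pValue, numeric(1))
  }
  out
}

#' Render the per-threshold core counts as a compact label
#'
#' Formats the "core groups per clustering threshold" summary as
#' `"97:17, 95:3, ..."`, listing only thresholds with at least one core.
#'
#' @param core A [PhylogeneticCore-class].
#' @return A single character string (empty if no cores).
#' @export
formatCoreGroups <- function(core) {
  stopifnot(is(core, "PhylogeneticCore"))
  if (length(core@cores) == 0L) return("")
  thr <- vapply(core@cores, function(co) co@detectionThreshold, numeric(1))
  tab <- table(factor(as.integer(round(thr * 100)),
                      levels = as.integer(round(core@thresholdGrid * 100))))
  tab <- tab[tab > 0]
  paste0(names(tab), ":", as.integer(tab), collapse = ", ")
}
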