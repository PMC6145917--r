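---
title: "Dynamic phylogenetic core detection: models, parameters and design"
author: "phylocore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic phylogenetic core detection: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocore)
```

## The question and the model

A recurring question in gut microbiome research is whether a *core*
microbiome exists: bacterial groups common to essentially all healthy
subjects. Fixed-threshold OTU analyses answer it only at one arbitrary
phylogenetic depth, and taxonomy-based answers inherit the biases and
uneven depths of taxonomic annotation. phylocore implements a dynamic
alternative: core units are sequence clusters detected over a whole ladder
of identity thresholds, so the core can contain both phylogenetically
shallow units (species-like, 0.97 identity) and deep units (family-like,
0.8x identity), each found at the highest depth at which it is universal.

The procedure is:

1. **Rarefaction.** Every sample is subsampled without replacement to the
   common (minimum) depth, so presence/absence is comparable across
   subjects.
2. **Ladder clustering.** Reads are clustered de novo at the top threshold
   (0.97); each lower level re-clusters the previous level's representative
   sequences (multi-step/chained picking), composing membership maps back
   to the original reads. OTU counts are therefore non-increasing down the
   ladder and each level's table partitions the reads.
3. **Dynamic core detection.** Visiting thresholds in descending order, an
   OTU whose (masked) count is positive in at least
   `ceiling(prevalence * n_samples)` samples is designated a core OTU
   (default prevalence 1: all samples). Before each level is evaluated,
   all reads already claimed by higher-threshold cores are masked out, so
   the reported core units are pairwise disjoint and pooled statistics
   never double-count a read.
4. **Significance.** The per-level core count is ranked within a null
   distribution obtained by shuffling each sample's abundance values
   across OTUs (sample richness and abundance multisets preserved), with
   the add-one empirical p-value `(1 + #{null >= obs}) / (1 + n)`.

```{r toy, eval = FALSE}
sim <- simulateDataset(defaultLineageSpecs(), nSubjects = 10,
                       depthPerSubject = 500, seed = 1)
core <- runDynamicCore(sim$dataset)
core
pooledCoreFrequency(core)
```

## The identity kernel

Clustering needs a pairwise identity definition. phylocore uses an exact
dynamic-programming alignment with scores match +1, mismatch −1, gap −2,
and reports identity = match columns / alignment columns, counting
internal gaps but not free terminal gaps. Identity can differ between
co-optimal alignments, so the kernel is made fully deterministic by a
lexicographic objective: maximize score, then match count, then prefer the
fewest columns. `N` never matches anything, including another `N`.

Terminal-gap handling deserves care. If terminal gaps are free on *both*
sequences (a pure overlap alignment), the optimal score between two
divergent random sequences is usually attained by a tiny perfect overlap —
a handful of columns, all matches — because the expected per-column score
of a long spanning alignment of unrelated DNA is negative under this
scoring. Such an alignment reports identity near 1 for unrelated
sequences, which destroys threshold clustering. The default mode is
therefore a *fit* (glocal) alignment: terminal gaps are free only on the
reference side, and the query must span the alignment end to end. Both
orientations are evaluated and the better one kept, so the measure is
symmetric; a read fully contained in a longer read still scores 1 (the
desired behavior for length-heterogeneous amplicons), while unrelated
250-mers score ≈ 0.5. The degenerate both-ends-free variant remains
available as `endGaps = "overlap"` for comparison.

## Clustering rules

Greedy centroid clustering processes items by decreasing weight (duplicate
count at the first level, accumulated original counts at chained levels),
ties broken by ascending id in the C locale. Each item is compared to all
existing centroids and joins the best one at or above the threshold (ties
to the earliest-created centroid), else founds a new OTU. This best-hit
rule, rather than a first-acceptable-hit search, was chosen because it is
reproducible and order-insensitive to centroid storage — greedy clustering
heuristics differ between tools precisely in these undocumented corners,
and determinism is what makes the pipeline's outputs byte-reproducible.
Exact duplicates are collapsed before the first level (weights
accumulate), which changes nothing in the result but removes most of the
quadratic cost. Identities are memoized across ladder levels (they do not
depend on the threshold), which makes the 23-level ladder roughly as cheap
as its first level.

## Masking semantics

Two readings of "remove all sequences belonging to previously detected
cores" are implemented. The default recomputes each level's table from the
chained origin maps over unclaimed reads only (*masking*): it is cheap,
deterministic, and keeps OTU ids stable across levels; an OTU whose masked
count vanishes still anchors chaining through its representative. The
alternative `recluster = TRUE` physically re-clusters the surviving reads
from scratch at every level. Because the ladder is chained, the two agree
on cleanly separated data (this is tested); the masking mode is the
reference behavior. Cores detected at one level are processed jointly —
their memberships are disjoint by the partition property, so claim order
within a level cannot matter.

## The permutation null

The null preserves, for every sample independently, the full multiset of
abundance values — zeros included — and permutes which OTU holds which
value. Row sums and sample richness are thus invariant; what is broken is
the cross-sample concordance of occupancy. This is the strictest null
consistent with "maintaining sample richness", and it is applied to the
same masked tables on which cores are counted. One hundred permutations
give a p-value floor of 1/101 ≈ 0.0099; the add-one correction keeps p
strictly positive. Calibration (p approximately uniform on tables
generated by the shuffle itself) and power (a single planted universal
column in a sparse 50 × 500 table at p ≤ 0.02) are asserted in the test
suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `thresholds` | 0.97 … 0.75 by 0.01 (23 levels) | 0.97 is the customary species proxy; below 0.75 nucleotide alignment quality degrades. Both endpoints are evaluated. |
| `prevalence` | 1.0 | fraction of samples a core must occupy; presence is count > 0, never a relative-abundance floor. `ceiling()` keeps fractional prevalence conservative on small cohorts. |
| `minLength` | 75 nt | reads shorter than this are rejected at read time; typical inputs are 100–250 nt amplicons and very short fragments make alignment identity unstable. |
| `nPermutations` | 100 | per-level null size; p-floor 1/101. |
| consensus `cutoff` | 0.51 | majority rule of the consensus-taxonomy walk. |
| `minConfidence` | 0.80 | per-sequence classifier confidence floor applied before voting. |
| `endGaps` | `"fit"` | identity kernel mode (see above). |
| `seed` | — | mandatory wherever randomness exists; one master seed derives stage-keyed seeds (`deriveSeed`), so a whole run is byte-reproducible. |

## The simulator and what it does (not) emulate

`simulateDataset()` generates multi-subject communities with known ground
truth so every stage is testable without external data. Its model:

- **Lineages** are built from random ancestors (250 nt by default, the
  typical V4 read length), accepted only if all pairwise ancestor
  identities are ≤ 1 − `minInterDivergence` (default 0.25), which keeps
  lineages separable over the whole clustering ladder.
- **Strain structure.** `intraDivergence` is the lineage's *diameter*:
  every strain differs from the ancestor at exactly
  `round(intraDivergence/2 × L)` uniformly chosen sites, so pairwise
  strain divergence ≈ `intraDivergence`. The exact-count model (rather
  than i.i.d. per-site substitution) removes binomial tail noise, so a
  diameter-0.02 lineage is *always* a single 0.97 cluster and a
  diameter-0.06 lineage never is. Each subject carries its own strain
  (round-robin assignment from the pool; by default one strain per
  subject), which is what places divergent lineages at mid-ladder depths:
  no single variant is universal, but the strains merge into one universal
  cluster once the ladder reaches the lineage's diameter.
- **Abundances** per subject are `baseAbundance ×
  lognormal(0, dispersion)` with dispersion 1 — a heavy-tailed
  across-subject variation typical of gut taxa. Sporadic lineages are
  included per subject with probability `occupancy` (default 0.5). Reads
  are drawn multinomially to an exact per-subject depth; universal
  lineages are guaranteed ≥ 1 read per subject (forced from the subject's
  largest lineage), so "universal" means detectable-universal at the
  simulated depth. The unforced regime — universality lost to shallow
  sequencing — can be explored by lowering `depthPerSubject`.

The default panel (`defaultLineageSpecs()`) is 5 universal + 15 sporadic
lineages with diameters cycling 0, 0.02, 0.06, 0.10. The validation suite
runs this at 10 subjects × 500 reads over 20 seeds — small enough to keep
the full suite in minutes, large enough that every ladder regime
(0.97-level cores, mid-ladder cores, sporadic non-cores) is exercised.

What the simulator deliberately omits: chimeras, per-base sequencing error
and quality scores, PCR/primer bias, indel variation (substitution-only by
default), phylogenetically correlated trait structure, and compositional
covariance between lineages. Passing tests therefore demonstrate the
*algorithmic* correctness of clustering, masking, prevalence logic and the
null model — not robustness to upstream artifacts, which the surrounding
QC tooling of an amplicon workflow must handle before this analysis.

## Numerical and degenerate-input choices

- Threshold comparisons use plain `>=` on exact rational identities
  (ratios of small integers); no epsilon is injected, and the reference
  implementation used in testing makes the same comparison, so agreement
  is exact.
- OTU ids are `T<threshold×100>_<k>` in creation order; per-level labels
  are formatted per element ("0.9", not a padded "0.90").
- Empty inputs: clustering an empty item set yields a valid empty result;
  an empty OTU set writes a parseable table; the ECDF of an empty vector
  and consensus over zero assignments are errors.
- A sporadic lineage that happens to occupy every subject *is* a true
  core; recovery evaluation counts it against precision only when judging
  planted-universal recovery, and the simulation tests accept the rare
  seeds where this occurs.
- `sd` is the sample standard deviation (n − 1) throughout, with a
  population-sd option on pooled frequencies; the sd over a single value
  is reported as 0 in reference-match aggregation.

## Known limitations

- Greedy centroid clustering is not transitive; different orderings can
  split borderline members differently. The deterministic rules make
  results reproducible, not canonical.
- The exhaustive O(n²·L²) alignment strategy suits desk-scale and
  representative-set comparisons; clustering millions of raw reads would
  need a k-mer prefilter, which is out of scope.
- Identity is one specific alignment definition; tools that count
  terminal gaps, or pick a different co-optimal alignment, will report
  slightly different values near thresholds.
- Consensus taxonomy consumes external per-sequence assignments; no
  classifier or reference database ships with the package.
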