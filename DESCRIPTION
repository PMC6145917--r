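Package: phylocore
Title: Dynamic Phylogenetic Core Detection for Pan-Microbiome Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the compositional core of a pan-microbiome as a set of
    discrete 16S rRNA sequence clusters (core OTUs) of varying phylogenetic
    depth. Sequences are clustered de novo over a descending ladder of
    identity thresholds by chained greedy centroid clustering; at each level,
    OTUs present in all subjects are designated core OTUs after masking all
    sequences already claimed by cores found at higher thresholds. The
    significance of per-level core counts is assessed by a richness-preserving
    within-sample permutation null. Includes consensus taxonomy from
    per-sequence assignments, reference 16S coverage reports, summary
    statistics, and a synthetic amplicon community simulator with planted
    ground-truth core lineages for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    Rcpp,
    jsonlite,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'phylocore-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'clustering.R'
    'core-detection.R'
    'permutation.R'
    'core-stats.R'
    'taxonomy.R'
    'refmatch.R'
    'simulate.R'
    'run-all.R'
    'seq-io.R'
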