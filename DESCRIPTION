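Package: hybridscan
Title: Local Ancestry Dynamics in Hybrid Genomes: Simulation, Genome
    Scans, and Demographic Inference
Version: 0.1.0
Authors@R:
    person("hybridscan", "developers", email = "hybridscan@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how hybrid genomes stabilize after
    admixture. Provides a tract-based Wright-Fisher forward simulator of
    admixed populations under configurable selection (hybrid
    incompatibility pairs, hybridization load, selection against one
    parental species), post-HMM processing of local ancestry calls
    (posterior hard-calling, site masking, Hardy-Weinberg filtering,
    ancestry-transition intervals, tract-length masking), windowed
    summaries of ancestry against genomic architecture with Spearman and
    Spearman partial correlations, detection of minor-parent ancestry
    deserts and islands with cross-population sharing classification and
    three permutation null schemes, rejection-based approximate Bayesian
    computation for admixture demography, and F2 intercross scans for
    segregation distortion and two-locus hybrid incompatibilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
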