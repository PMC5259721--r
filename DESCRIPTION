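Package: exocohort
Title: Simulation and Rare-Variant Association Analysis of Case/Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case/control exome association studies built around a
    synthetic-cohort simulator with known ground truth. Simulates two-subpopulation
    cohorts under the Balding-Nichols model with block LD, a rare-heavy site
    frequency spectrum and an additive logistic disease model; applies variant and
    sample quality control (site call rate, minor allele frequency, method-of-moments
    relatedness pruning, ancestry principal components); runs single-variant Fisher
    and covariate-adjusted logistic association with inflation diagnostics; performs
    gene-level variance-component (kernel) burden testing with Beta(1,25) minor
    allele frequency weights; and implements matched-permutation enrichment tests
    for gene sets, LD-defined GWA intervals and tissue expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
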