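Package: oriterscan
Title: Coverage-Based Duplication Detection and Origin-Terminus Expression
    Domain Analysis for Bacterial Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting large segmental duplications on circular
    bacterial chromosomes from sequencing read depth, and for relating gene
    expression to chromosome architecture. Implements mode-based coverage
    normalization over fixed-width bins, the Rc origin-to-terminus coverage
    ratio, change-point detection of duplication boundaries, inference of the
    prevalence of a duplication within a mixed population of genomic DNA
    molecules, a binomial likelihood ratio discriminating duplication from
    deletion scenarios, dosage-aware mode size factors for differential
    expression with an exact conditional binomial test, permutation-based
    positional gene-set enrichment in sliding chromosomal windows, and
    compendium-wide pairwise correlation analysis that partitions the
    chromosome into two anti-correlated expression domains. A synthetic-data
    module generates coverage tracks, replicate count matrices and expression
    compendia with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    BiocGenerics,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
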