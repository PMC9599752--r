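Package: fourcquant
Title: Viewpoint-Based 4C-seq Contact Quantification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies chromatin contacts from circular chromosome
    conformation capture sequencing (4C-seq) viewpoints. Builds restriction
    fragment maps by in-silico double digestion (e.g. NlaIII/DpnII), converts
    aligned reads to per-fragment contact scores with viewpoint exclusion,
    normalizes scores to the local mean around the bait, smooths tracks with
    a running mean, corrects for the power-law decay of contact frequency
    with genomic distance using a fixed slope of -1 in log-log space, and
    tests for differential contacts between two conditions inside a target
    region with a D'Agostino-Pearson normality gate and an unpaired
    two-tailed Mann-Whitney test. Includes a synthetic-data generator that
    emulates fragment-level 4C count profiles (overdispersed counts, a
    planted contact peak) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
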