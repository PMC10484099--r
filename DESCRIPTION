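Package: capmeth
Title: Targeted Methylation Capture Panel Design, Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for hybridization-capture probe panels over
    methylation targets: fixed-length probe tiling at a chosen density,
    consensus repeat masking across multiple maskers, GC-based probe
    boosting and in-silico coverage accounting. A seeded simulator
    generates diploid genomes with a variant-dense region, bimodal CpG
    methylation and probe-weighted capture of bisulfite- or
    enzymatically-converted fragments, so the downstream workflow is
    testable end to end: strand-merged CpG quantification,
    conversion-efficiency QC from non-CpG cytosines, differential
    methylation calling with a cross-method consensus rule, and
    coverage-filtered bisulfite-aware diploid genotyping with replicate
    concordance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
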