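Package: mirtrio
Title: Triangulating miRNA Targets from Expression, RISC Pulldown, and
    Prediction Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate microRNA target genes by intersecting three
    independent lines of evidence: a fold-change downregulation screen on
    stable-cell RNA-seq counts (quantile normalized), enrichment in a
    RISC-trap pulldown quantified by the R_RC log2 ratio-of-read-counts
    statistic with a control-calibrated quantile threshold, and a consensus
    vote over target-prediction algorithms. Includes a negative-binomial
    synthetic-data generator with planted targets for end-to-end validation,
    and helpers for extracellular-vesicle quantification: top-k aggregation
    of TRPS particle-concentration replicates, copies-per-vesicle arithmetic,
    and qPCR standard-curve fitting and inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
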