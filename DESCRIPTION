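Package: capcnv
Title: Read-Depth CNV and Homeologous Exchange Calling from Targeted
    Sequence-Capture Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Calls copy number variants (CNVs) from per-region read counts of
    targeted sequence-capture experiments across large diversity panels of
    allopolyploid genotypes. Coverage is normalised by library size, region
    length and genome length, then per-genotype deletion and duplication
    states are called relative to the panel mean with a ratio rule. Coupled
    duplication-deletion calls between homeologous gene copies on the two
    subgenomes are classified as directional homeologous non-reciprocal
    translocations (HNRTs). Includes target-enrichment quality-control
    metrics (enrichment factor, target specificity and sensitivity),
    population CNV frequency spectra, subgenome bias summaries, marker
    recoding with call-rate and allele-frequency filters, cross-platform
    concordance rates, a synthetic-panel generator with planted events and
    known truth for benchmarking, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
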