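Package: tsrnaflow
Title: Identification, Classification and Regulatory Analysis of tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for the analysis of tRNA-derived small
    RNAs (tsRNAs) in bulk small-RNA sequencing data, built around a comparison
    of two tissue groups such as subcutaneous versus visceral white adipose
    tissue. Provides tRNA reference models with cloverleaf landmarks, a
    tRNA-space read aligner, a nine-type tRF/tiRNA classifier, a negative
    binomial conditional exact test for differential expression, seed-region
    base-preference profiling, nearest-neighbor duplex energy target
    prediction, anti-correlation regulatory network construction,
    over-representation and gene set enrichment analysis, parental amino-acid
    versus coding-sequence amino-acid usage correlation, and a synthetic data
    generator with full ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
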