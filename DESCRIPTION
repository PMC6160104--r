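Package: cnvpop
Title: Population Genetics of Copy Number Variation from SNP-Array Signal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for population-genetic analysis of copy
    number variants (CNVs) called from high-density SNP-array intensity data.
    Provides per-sample signal quality control (call rate, derivative log
    ratio spread, GC-wave factor, LRR standard deviation), aggregation of
    per-sample CNV calls into CNV regions (CNVRs) with gain/loss/complex
    classification and length/frequency summaries, cross-population region
    comparison, construction of individual-by-CNVR matrices under
    presence/absence or total-copy-number encodings, population-structure
    summaries (PCA, UPGMA clustering with bootstrap support), a V_ST scan
    for population-differentiated CNV regions, gene/QTL interval annotation,
    and a multi-breed synthetic cohort generator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
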