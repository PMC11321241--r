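Package: stemwalk
Title: Network Propagation Prioritization of Cancer Stemness-Associated
    Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs cancer-specific co-expression and regulatory
    networks from an expression matrix and curated interaction lists,
    prioritizes stemness-associated non-coding RNAs by random walk with
    restart from stemness seed genes, and calls significant predictions
    with a pseudo-seed permutation null. Includes median-split
    differential expression by stemness index, hypergeometric enrichment
    of predictions in differentially expressed ncRNA sets, and a
    single-factor synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
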