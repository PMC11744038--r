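Package: ervscan
Title: Subfamily-Level Expression Analysis of Endogenous Retroviruses from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intergenic endogenous retrovirus (ERV) expression at
    RepeatMasker-subfamily resolution from aligned RNA-seq, calls
    condition-specific upregulated subfamilies with a Welch t-test and Holm
    step-down adjustment plus a fold-change threshold, and tests whether
    upregulated subfamilies are evolutionarily younger (lower RepeatMasker
    divergence) than the remainder with a two-tailed Mann-Whitney U test.
    Includes RepeatMasker .out and GTF readers, strand-aware fragment
    counting over subfamily meta-features, FPKM normalization, a
    negative-binomial read/count simulator with planted effects for
    validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    tools,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
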