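Package: faireqtl
Title: Chromatin Accessibility QTL Mapping for Yeast Cross Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of chromatin accessibility in a
    two-parent haploid yeast cross. Consolidates per-strain FAIRE-seq peak
    calls into a unified set of open chromatin regions (OCRs), quantifies and
    normalizes per-strain accessibility, genotypes each OCR from SNP profiles,
    decomposes accessibility variation into sequence-dependent (cis) and
    sequence-independent (trans) components, maps chromatin and expression
    QTLs by correlation with a permutation-based empirical false discovery
    rate, detects multi-target (hotspot) regulatory loci, and computes
    genomic-context statistics (gene density, telomere-distance profiles,
    recombination hotness, poly-A/T tracts, motif-polymorphism enrichment).
    Ships a synthetic cross generator with ground-truth effect tables so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    IRanges,
    S4Vectors,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
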