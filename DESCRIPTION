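Package: cellwise
Title: Cell-Composition Estimation and Confounding Assessment for Bulk Brain Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type composition of bulk brain tissue from three
    omics modalities: marker gene profiles (MGP) from RNA-seq expression,
    marker site profiles (MSP) from H3K27ac ChIP-seq reads-in-peaks, and a
    methylation-based analogue (WGBS MSP), together with a constrained
    reference-based comparator. Provides the machinery to derive cell-type
    marker sites from sorted-nuclei differential acetylation, to compare
    estimates across methods and modalities, to fit case-control differential
    acetylation models under competing cell-composition adjustments, and to
    quantify residual composition bias against cell-type-specific reference
    regions. Ships a multi-omic simulator with known ground-truth
    compositions, including adjacent-tissue-sample decorrelation, a
    whole-tissue neuropil signal component absent from nuclear modalities,
    and condition-confounded neuronal loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
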