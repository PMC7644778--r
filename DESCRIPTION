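Package: spikequant
Title: Quantitative Metagenomics with Internal Genomic Standards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Turns annotation hit tables from spike-in calibrated marine
    metagenomes into volumetric microbial abundances. Implements internal
    genomic standard read identification and recovery ratios, single-copy
    gene (recA) genome-equivalent estimation, per-standard confidence
    intervals and detection limits, family-level abundance classes,
    first-party Bray-Curtis PERMANOVA and multivariate dispersion tests,
    compositional PCA, mixed-layer depth from CTD profiles, and a
    ground-truthed community and sequencing simulator for end-to-end
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
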