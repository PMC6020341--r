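Package: cginoise
Title: Gene Expression Noise and CpG Island Promoter Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cell-to-cell gene expression noise from single-cell
    RNA-seq counts as a mean-adjusted residual squared coefficient of
    variation (rCV2), screens promoter and gene-structure features --
    in particular CpG island presence and size -- against noise with robust
    linear models, classifies promoters as active, repressed or bivalent
    from H3K4me3/H3K27me3 ChIP enrichment, and tests whether short CpG
    islands are enriched among the earliest up-regulated genes in
    stimulation time courses.  A synthetic-data module generates all inputs
    with known ground truth so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    scran
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
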