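Package: sabrscreen
Title: Design and Analysis of Pooled SABR-II Epitope Screens for CD4+ T Cell
    Antigen Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for pooled epitope screens built on signaling and
    antigen-presenting bifunctional receptors (SABR-II) displaying peptide-MHC
    class II. Covers the full computational workflow: curation of defined
    epitope lists and enumeration of theoretical hybrid insulin peptide (HIP)
    libraries; back-translation of peptides into cloning-ready oligo pools
    avoiding restriction motifs; reconstruction of full-length TCRa-2A-TCRb
    constructs from V/J allele calls and CDR3 sequences against an IMGT-style
    segment reference; dual-index demultiplexing, flank-anchored insert
    extraction and counting of amplicon sequencing reads; control-calibrated
    enrichment-score (ES) computation with two-tier hit calling and dropout
    deconvolution of multiplexed screens; and a full screen simulator with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
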