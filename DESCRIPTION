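Package: mbdqc
Title: Quality Control for MBD-Based Methylation Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence-level quality evaluation of methyl-CpG
    binding domain (MBD) capture sequencing experiments (MBD-seq /
    MethylCap-seq). Reconstructs mapped fragments from paired-end
    alignments, collapses PCR duplicates, tabulates sequencing yield, and
    computes the Fragment CpG-plot - the normalized histogram of CpG
    counts per mapped fragment used as a yield-independent proxy for
    capture sensitivity and specificity. Also computes fraction profiles
    of fragments over binned independent methylation degrees (RRBS-like
    counts or array-like beta values), the corresponding background
    profile and their enrichment ratio, and ships a seeded simulator of
    MBD capture experiments (CpG-island genome model, bimodal island
    methylation, affinity capture, PCR duplicates, RRBS-like ground
    truth) so the whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
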