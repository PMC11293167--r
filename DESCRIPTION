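Package: secrescreen
Title: Design and Analysis of Pooled CRISPR-Cas9 Secretome Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for planning and analysing pooled CRISPR-Cas9 knockout
    screens aimed at reducing the secretome of a protein-production host
    such as the yeast Komagataella phaffii. The package defines a secretome
    by merging signal-peptide predictions with mass-spectrometry detection,
    designs genome-unique sgRNA spacer libraries against annotated coding
    sequences, quantifies guides from amplicon sequencing, scores per-gene
    essentiality with a one-sided two-sample Kolmogorov-Smirnov depletion
    test on guide log2 fold changes, runs weighted running-sum gene-set
    enrichment on the scores, selects non-essential knockout targets, and
    packs them into multiplexed delivery vectors. A synthetic-data module
    generates genomes, abundance tables and screen counts with known ground
    truth so the whole pipeline runs end-to-end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    GenomicRanges,
    ggplot2,
    grid,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
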