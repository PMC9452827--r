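Package: spliceshift
Title: Triage of Exonic Variants for Splicing Disruption and Exon-Skipping
    Consequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening exonic single-nucleotide variants for
    potential effects on pre-mRNA splicing and for predicting the protein
    consequence of the exon skipping they may cause. Provides HGVS cDNA
    variant parsing and exon-coordinate mapping on transcript models,
    position-weight-matrix and k-mer splice-site scoring with wild-type to
    mutant deltas, exonic splicing enhancer/silencer motif-delta scanning,
    a two-criterion candidate filter (boundary proximity or regulatory
    element disruption), frame-status and premature-termination prediction
    for skipped exons, and quantification of minigene (exon-trap) assay
    band intensities with pooled t-test comparison. A synthetic-data
    generator produces transcripts, variants and assay replicates with
    known ground truth so every stage can be tested without downloads.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
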