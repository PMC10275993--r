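Package: basicrepeats
Title: Periodic Basic-Residue Repeat Scanning and Charge-Feature
    Analysis of Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects maximal tandem periodic basic-residue motifs such as
    (X-R/K) dipeptide repeats in protein sequences, tests repeat-bearing
    proteins for overrepresentation in membrane-less-organelle localization
    categories with exact hypergeometric statistics, computes per-protein
    charge features (Henderson-Hasselbalch net charge, isoelectric point,
    longest contiguous D/E stretch, amino-acid composition with background
    normalization), and compares the charge features of the most and least
    enriched extremes of a ranked two-condition interactome. Ships a seeded
    synthetic-proteome generator with planted repeats, localization labels
    with a controlled odds ratio, and acidic-stretch-driven intensity
    tables, so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
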