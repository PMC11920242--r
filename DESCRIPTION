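Package: styscreen
Title: Design and Analysis of Adenine Base-Editing Screens for S/T/Y Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale adenine base editor (ABE) screens that
    tile serine, threonine and tyrosine residues with missense-generating
    sgRNAs. Covers sgRNA library design against coding sequences (editing
    window, NGG PAM, sense and antisense sub-libraries, internal barcodes
    and safe-harbor controls), enrichment scoring of sgRNA-iBAR count
    tables from FACS-sorted screens (median-of-ratios normalization,
    per-iBAR fold changes, consistency-penalized combination, BH-adjusted
    signed screen scores and hit calls), quantification of editing
    outcomes from amplicon sequencing (read-pair merging, flank-anchored
    target extraction, per-position base composition, codon-level
    amino-acid outcome calls), flow-cytometry and competitive T-cell
    killing phenotype metrics, weighted expression-signature construction
    and scoring with immune-marker correlation, and synthetic-data
    generators with machine-readable ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
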