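Package: dcsvquant
Title: Spectral-Count Quantitation of Dense-Core Secretory Vesicle Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Label-free quantitative proteomics pipeline for organelle
    proteomes profiled by GeLC-MS/MS with replicate gel lanes and gel
    slices, as applied to dense-core secretory (chromaffin) vesicles.
    Implements target-decoy filtering of peptide-spectrum matches with
    per-charge score thresholds and a two-peptide rescue rule, score-binned
    false discovery rate estimation, single-linkage sequence-identity
    clustering with minimal-redundant (parsimony) protein inference,
    normalized spectral abundance factor (NSAF) quantitation with a
    replicate-observation rule and zero-filled standard deviations,
    soluble/membrane differential (Diff-NSAF) classification, functional
    category summaries, marker-based organelle purity estimation, and
    export of node attributes for protein-interaction network tools. A
    synthetic-data generator emulates the experimental design (two
    fractions, four replicate lanes, eight gel slices) so the whole
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
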