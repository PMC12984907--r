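Package: repurposeR
Title: Genomic Alteration-Based Drug Repurposing for Stratified Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that nominates drug repurposing candidates
    from gene-level tumor genomics. Per patient stratum (e.g. HPV-positive and
    HPV-negative head and neck cancer), significantly amplified, deleted and
    mutated genes are identified with dual binomial and permutation tests under
    Benjamini-Hochberg false discovery control, prioritised by composite
    amplitude-times-frequency scores, expanded to high-confidence
    protein-protein interaction neighbors, validated against literature-derived
    gene evidence, and finally matched to drugs by hypergeometric and
    permutation enrichment of drug target sets. A synthetic-data module
    generates every input format with planted signal and known ground truth so
    the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
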