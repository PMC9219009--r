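Package: arfnet
Title: Gene-Ontology Network Maps and Target Inference for Auxin Response Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for identifying context-relevant transcription
    factors from Gene Ontology annotation files by keyword mining, grouping them
    into families by neighbor-joining clustering with bootstrap support,
    inferring their putative downstream target genes from co-expression and
    auxin-response-element (AuxRE) promoter motif criteria with exact
    position-weight-matrix p-values, building hypergeometric GO "biological
    process" enrichment network maps, and comparing root-related node content
    across transcription-factor query sets. Also implements the accompanying
    wet-data statistics: delta-delta-Ct relative quantification of qPCR data
    with Mann-Whitney significance, and chi-square goodness-of-fit analysis of
    transgene segregation ratios. A fully deterministic synthetic-data module
    generates every input format (OBO ontology, annotation table, promoter
    FASTA with planted motifs, block-correlated expression, Ct tables,
    segregation counts) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
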