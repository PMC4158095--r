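Package: tagdge
Title: Digital Gene Expression Tag-Seq Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis of restriction-anchored digital gene
    expression (DGE-tag / SAGE-style) libraries. Builds reference tag
    databases of all CATG + 17 nt 21-mers from transcript and genome FASTA,
    filters raw tags into clean libraries, maps tags with an optional single
    mismatch, quantifies genes as tags per million clean tags (TPM), calls
    differentially expressed genes with an empirical noise-distribution
    probability statistic, performs hypergeometric term enrichment, and
    computes between-species log-ratio matrices with hierarchical
    clustering. Ships a fully ground-truthed simulator of a two-species,
    three-stage, two-replicate tag-sequencing experiment so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
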