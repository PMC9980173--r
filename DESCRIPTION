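Package: scabatlas
Title: Single-Cell 3D Genome Lifespan Atlas Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-cell chromosome-conformation
    (Dip-C style) contact data across the lifespan: per-cell chromatin A/B
    compartment scores (scA/B) on a 1-Mb grid, hierarchical structure typing
    and five-stage (S1-S5) granule-cell staging, contact distance-decay
    statistics including the ultra-long-range (>=10 Mb) contact fraction,
    aggregated and relative-change contact maps, inter-chromosomal
    enrichment and multi-chromosome hub detection, stage-resolved scA/B
    trajectory analysis, and demultiplexing of pooled donors by X:A contact
    density and SNP genotypes. Includes a calibrated synthetic contact
    generator that plants compartment checkerboards, stage-specific
    distance-decay mixtures, inter-chromosomal hubs, sex differences and
    pooled-donor allele observations, so every stage of the pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    Rtsne,
    withr,
    uwot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
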