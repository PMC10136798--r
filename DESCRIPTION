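Package: circArch
Title: Backsplice Junction Classification, Host-Gene Architecture, and
    RNAPII Pausing Analysis for Circular RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how circular RNA (circRNA) biogenesis relates
    to host-gene architecture and RNA polymerase II dynamics. Classifies
    backsplice junction calls against a gene annotation into intronic and
    exonic (single- or multi-exon) circRNAs, profiles flanking-intron
    length asymmetry, scans flanking introns for G-quadruplex motifs,
    repeat-element enrichment, and symmetric RNA-binding-protein motifs,
    computes RNAPII pausing indices from strand-resolved nascent-RNA
    coverage over a circRNA-anchored region schema, and quantifies
    circular-to-linear transcriptional output from hybridization-based
    probe counts. Includes a deterministic synthetic-data generator that
    emulates all input formats with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneRegulation, Sequencing, Coverage,
    AlternativeSplicing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'architecture.R'
    'circArch-package.R'
    'classify.R'
    'fixtures.R'
    'formats-io.R'
    'gtf-io.R'
    'output-ratio.R'
    'pausing.R'
    'pipeline.R'
    'sequence-bias.R'
    'simulate.R'
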