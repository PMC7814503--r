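Package: envmeta
Title: Multi-Environment GWAS Meta-Analysis and Growth-Habit Classification for Barley
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping low temperature tolerance and vernalization
    sensitivity in barley association panels scored across many field
    environments. Implements per-environment single-marker association scans
    with principal-component and kinship correction (P3D/EMMAX-style mixed
    model), Fisher's combined-probability meta-analysis across environments
    with Benjamini-Hochberg false discovery rate control, linkage
    disequilibrium decay estimation against an unlinked-marker threshold,
    two-locus epistasis likelihood-ratio tests, neighbor-joining clustering
    on identity-by-state distances, and the explicit vernalization-response
    and growth-habit classification rules (VRN-H1, VRN-H2, PPD-H1, PPD-H2
    allele calls). A synthetic panel generator with known ground truth makes
    every pipeline stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'classify.R'
    'fixtures.R'
    'interactions.R'
    'io.R'
    'ld.R'
    'meta.R'
    'simulate.R'
    'structure.R'
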