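Package: GermplasmVarKit
Title: Population SNP Annotation, Concordance and Structure Analysis for
    Germplasm Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and characterizing population-scale SNP
    resources from diverse germplasm collections of a crop and its wild
    relative. Implements per-genotype and per-site quality filters (depth,
    site quality, SNP-cluster windows, minor allele frequency and missing
    rate), a 30-category structural and functional SNP annotation engine
    (codon consequence, premature stop, splice site, per-subpopulation
    allele frequencies, deleteriousness flagging), cross-platform genotype
    concordance with best-match "genomic equivalent" accession assignment
    and duplicate detection, population characterization (identity-by-state
    distances, neighbor-joining trees, principal component analysis,
    linkage-disequilibrium pruning and decay curves) and a PC-adjusted
    single-marker association scan with Bonferroni thresholding. A
    synthetic-data generator emulates a two-subpopulation wild/cultivated
    collection with planted ground truth so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
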