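Package: cypcensus
Title: Census and Classification of Bacterial Cytochrome P450 Complements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide census analysis of cytochrome P450
    monooxygenases (CYPs) in bacterial proteomes. Implements the
    nomenclature-committee identity rule (same family above 40 percent
    identity, same subfamily above 55 percent) as an incremental
    best-hit classifier over a reference database of named P450s,
    aggregates classifications into family/subfamily census tables with
    diversity and biosynthetic-gene-cluster (BGC) statistics, builds
    presence/absence profiles with hierarchical clustering, calls P450
    membership in BGC regions by interval containment, and reconstructs
    pathway presence from best-homolog identity, similarity and
    coverage. Includes a synthetic-data generator producing proteomes
    and genomes with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, Clustering, Annotation, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
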