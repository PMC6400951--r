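Package: svlineage
Title: Structural Variant Lineage Analysis of Multi-Histology Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs clonal lineage relationships between micro-dissected
    histologic components of a tumour from mate-pair sequencing structural
    variant junctions. Provides junction detection by orientation-aware
    clustering of discordant fragments, quality/size/genic-region filtering
    with cross-sample rescue, germline subtraction against a matched normal,
    shared/unique junction matrices and component dendrograms, arm-level
    copy-number karyotyping (including multi-copy 12p gain detection),
    copy-neutral loss-of-heterozygosity calling from SNP allele fractions, and
    somatic mutation filtering with shared-mutation counting. A synthetic
    clone-phylogeny data generator with full ground truth makes every stage
    testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
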