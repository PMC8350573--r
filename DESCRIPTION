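Package: prionet
Title: Prionome Detection and Layered Regulatory Network Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects prion-like domains in proteomes by compositional
    log-likelihood window scoring, summarizes prionomes (density, functional
    categories, transposon/retrotransposon share), builds signed dual-method
    (Pearson + Spearman) co-expression networks from diurnal expression
    matrices, extracts strand-aware promoter regions from genome annotation,
    filters candidate regulatory edges by promoter cis-binding evidence,
    assembles the three-layer gene regulatory network, and extracts dense
    clusters with an MCODE-style algorithm. Includes deterministic synthetic
    data generators (proteomes with planted Q/N-rich domains, diurnal
    matrices with planted co-expression modules, genomes with planted
    promoter motifs, role tables) with ground-truth tables for recovery
    testing, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
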