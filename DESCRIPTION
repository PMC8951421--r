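Package: TADfunc
Title: Functional Similarity of Genes in Topologically Associating
    Domains and Spatially Proximate Genomic Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether protein-coding genes that share a
    topologically associating domain (TAD), an inter-TAD gap region, or a
    long-range spatial contact also share functions. Implements gap-region
    derivation and gene-to-domain assignment on top of GenomicRanges,
    GO-based gene-pair semantic similarity (Wang-style with
    topology-dependent edge weights), expression-similarity scoring,
    functional-similarity-network communities with the same-TAD-belonging
    ratio, Hi-C-derived gene-gene spatial interaction networks, a linear
    graph autoencoder for network reconstruction and link prediction,
    neighbor-voting gene function inference, detection of strongly and
    weakly interacting long-range region pairs, and seeded synthetic-data
    generators that emulate all required inputs with planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
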