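Package: retrobgc
Title: Retro-Biosynthesis-Guided Identification of Fungal Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the biosynthetic gene cluster (BGC) responsible for a
    polyketide natural product by working backwards from the compound's
    structure. An annotated polyketide chain specification is decomposed into
    the domain inventory an iterative highly reducing type I polyketide
    synthase (HR-PKS) must carry; the genome's gene models are scanned for that
    architecture; co-localized candidate clusters (two HR-PKSs plus a
    transferase) are filtered by a stage-specific expression signature (silent
    during active growth, expressed in stationary phase); and cluster borders
    are called from gene-level coregulation. Includes molecular-formula and
    monoisotopic-mass bookkeeping, RPKM-based expression categorization with
    TMM normalization and a two-condition differential test, a negative
    binomial synthetic-genome/count simulator for validation, and a
    deterministic reference dataset encoding the rasfonin cluster locus of
    Chalara gorgonifer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
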