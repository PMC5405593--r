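Package: bzipr
Title: Annotation of Plant bZIP Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the basic-hinge core of bZIP transcription-factor
    domains in protein sequences from its invariant motif (N-X7-R/K-X9),
    establishes the conventional -18..-1/+1 position numbering, registers
    leucine-zipper heptads (gabcdef) and predicts dimerization properties
    from attractive/repulsive g-e' pair classification, derives intron
    splice phases from gene models and classifies the five intron
    placement patterns of the basic-hinge region, and computes standard
    ProtParam-style protein descriptors (molecular weight, theoretical pI,
    instability index, aliphatic index, GRAVY). Includes a synthetic-data
    generator that plants fully known domain structure, zipper registers,
    pair categories and intron patterns so every stage of the pipeline can
    be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
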