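Package: gsTailSeq
Title: Gene-Specific TAIL-Seq Uridylation Calling and mRNA Decay Kinetics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-specific TAIL-Seq analysis of mRNA 3' ends:
    simulation of 3'-end sequencing reads with the anchor/poly(A)/non-templated
    addition/linker library structure, per-read calling of poly(A) tail length
    and terminal non-templated additions (mono- and oligo-uridylation, cytosine
    and guanine addition), aggregation into per-condition uridylation
    frequencies and poly(A)-length-binned correlation statistics, and mRNA
    half-life estimation from actinomycin-D chase RT-qPCR time courses with
    delta-delta-Ct normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
biocViews: Transcriptomics, Sequencing, RNASeq, GeneExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
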