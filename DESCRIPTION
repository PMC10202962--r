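Package: atacircle
Title: Detection of Extrachromosomal Circular DNA from ATAC-Seq Alignments
Version: 0.9.0
Authors@R: person("atacircle", "developers", role = c("aut", "cre"),
    email = "atacircle@example.org")
Description: Reconstructs extrachromosomal circular DNA (ecDNA) structures
    from paired-end ATAC-Seq alignments. Calls depth-enrichment regions with
    a global Poisson background model, clusters discordant read pairs into
    junction evidence regions, refines breakpoint positions with a combined
    uniform-maximum ("German tank") and clipped-read normal model, and
    enumerates candidate circles by an alternating-edge depth-first search
    over a two-edge-type breakpoint multigraph. Ships a circular-template
    read simulator with a perfect-alignment SAM writer and a
    precision/recall/F1 evaluator so the whole pipeline can be benchmarked
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
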