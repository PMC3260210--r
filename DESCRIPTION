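Package: AcDsTools
Title: Structure-Based Discovery and Annotation of Ac/Ds Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery, classification and annotation of hAT-superfamily
    Ac/Ds transposable elements from genome sequence alone. Elements are
    called from paired 11-bp terminal inverted repeat (TIR) motifs flanked
    by an 8-bp target site duplication (TSD), classified into Ac-like,
    Ds1, Ds2, Ds-l3 and Ds-l4 structural classes by homology profiling
    against a reference Activator element, and annotated for insertion
    context, internal cargo (retrotransposon insertions, captured gene
    fragments, nested elements, filler DNA) and compound structure.
    Includes subterminal AAACGG hexamer scoring, transposon-display
    junction matching across genomes, neighbour-joining clustering of
    filler sequences, and a fully seeded synthetic-genome simulator with
    ground truth for benchmarking every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Annotation, SequenceMatching, Transposon, Software
RoxygenNote: 7.3.3
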