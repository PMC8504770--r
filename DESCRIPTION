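Package: TEmobilome
Title: Transposable Element Mobilome Survey: Coverage, Copy Ages, MITEs
    and Gene Context
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying the transposable-element (TE) content of a
    draft genome assembly. Provides coverage accounting over TE copy
    annotations with full-length-copy (FLC) filtering of the consensus
    library; master-slave multiple alignment of family copies against their
    consensus via global affine-gap alignment; copy-age estimation in
    substitutions per base pair from terminal-fork (cherry) pairs of
    neighbor-joining family trees, with transposition-burst detection on
    the age distribution; structural discovery of miniature inverted-repeat
    transposable elements (MITEs) from terminal inverted repeats (TIRs) and
    target-site duplications (TSDs) with greedy family clustering and
    superfamily assignment; and classification of TE insertions relative to
    genes with sense/antisense orientation tests. A seeded synthetic
    mobilome generator produces genomes, TE families, copies, MITEs and
    genes with known ground truth so every stage can be validated end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Annotation, SequenceMatching, Alignment,
    Phylogenetics
RoxygenNote: 7.3.3
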