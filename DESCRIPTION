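Package: cpjunctions
Title: Junction-Site Analysis and Visualization for Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the quadripartite (LSC-IRb-SSC-IRa) structure of complete
    chloroplast genome records regardless of where the deposited linearization
    starts, including records whose regions wrap the sequence origin. Genomes
    are normalized by a canonical k-mer single-copy scan and rotation, the
    inverted-repeat arms are located with a native seed-and-extend exact-match
    finder, coordinates are mapped back to the deposited orientation, and the
    start is standardized to the first base of the large single-copy region.
    The four junction sites (JLB, JSB, JSA, JLA) are computed together with
    their flanking genes, distances, and strands, and rendered as a stacked
    multi-genome diagram (SVG, with PDF/PNG renditions) that makes
    inverted-repeat expansion and contraction visible. A synthetic plastome
    generator produces ground-truth annotated GenBank fixtures covering all
    nine starting-point groups.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grid,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
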