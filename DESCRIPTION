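Package: orgc
Title: Plant Organellar Genome Assembly from Whole-Genome Shotgun Contig Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers complete circular chloroplast and mitochondrial genomes
    from whole-genome shotgun assembly output without organelle isolation.
    Contigs are classified by read depth (organellar genomes are present in
    many copies per cell, so their contigs sequence deeper than nuclear
    contigs), the contig connection graph is pruned of false links and forks,
    the circular traversal is found by exhaustive walk search with repeat
    multiplicities inferred from depth ratios, plastid quadripartite structure
    (LSC/SSC/inverted repeats) is annotated, and dispersed mitochondrial
    repeats are resolved into a master circle using mate-pair link counts via
    maximum-weight flank matching. Includes readers for GFA 1 and a
    Newbler-style contig-graph table, a synthetic planted-genome simulator for
    validation, and a sequencing-subsampling coverage experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
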