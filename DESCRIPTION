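Package: rgascape
Title: Receptor-Like Kinase and Protein Gene Landscape Analysis in
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("rgascape", "maintainers", email = "rgascape@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of the receptor-like kinase (RLK) and
    receptor-like protein (RLP) resistance gene analogue families in an
    allotetraploid genome and its diploid progenitors.  Classifies genes
    into LRR/LysM RLK and RLP subfamilies from domain-architecture tables,
    detects positional gene clusters under a distance-chaining rule, calls
    and types duplicate gene pairs (tandem, segmental, dispersed;
    intra- versus inter-subgenomic), identifies paralogs and orthologs from
    BLAST-style similarity tables, accounts for subgenome conservation,
    gain and loss against progenitor genomes, detects chromosome-level
    synteny chains, and builds distance-based neighbour-joining trees.
    Includes a deterministic allopolyploid genome simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    ape,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
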