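Package: pancore
Title: Pan-Genome and Core-Genome Analysis of Multi-Replicon Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative pan-genomics for multi-replicon bacteria: protein
    family construction by Markov clustering (MCL) of an all-vs-all local
    alignment similarity graph with Karlin-Altschul e-value statistics,
    reciprocal-best-hit core-genome inference with coverage and similarity
    floors, replicon summary statistics and chromosome/chromid/plasmid
    classification, and Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction for purifying-selection analysis. Includes a
    codon-level synthetic pan-genome generator with known family, orthology,
    origin and selection ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
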