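Package: repeatomeKit
Title: Comparative Repeatome Analysis from Genome-Skimming Read Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream comparative analysis of plant repeatomes estimated
    from low-coverage genome-skimming read clustering. Provides genome-size
    arithmetic (2C/1Cx, pg/Mbp), descriptive and rank-based statistics over
    repeat-abundance tables, observed/expected interspecies edge-ratio
    matrices from read-similarity (hitsort) graphs with Euclidean and
    inverse-similarity distance transforms, neighbor-joining trees and
    consensus split networks, Blomberg's K phylogenetic-signal tests with
    permutation calibration, phylogenetically independent contrasts for
    repeat-amount versus genome-size correlation and pairwise contribution
    estimates, per-read intraspecific/interspecific (Hs/Ho) similarity-hit
    ratio profiling, and graph-topology classification of tandem-repeat
    (5S rDNA-like) clusters. A seeded synthetic-data generator emulates
    comparative read-clustering outputs so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phytools,
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
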