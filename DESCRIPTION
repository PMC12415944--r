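Package: delimscale
Title: Single-Locus Species Delimitation and Its Scaling from Genes to
    Organelle Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how single-locus species delimitation methods
    behave as alignments grow from individual genes to whole organelle
    genomes. Implements three delimitation engines from first principles: a
    barcode-gap ranking method in the spirit of ASAP (single-linkage
    candidate partitions scored by permutation panmixia probabilities and
    relative gap width), the single-threshold general mixed Yule-coalescent
    (GMYC) model with a profiled waiting-time likelihood and coalescent
    branching-rate diagnostics, and maximum-likelihood Poisson tree
    processes (PTP) with greedy and exhaustive partition searches. A
    multispecies-coalescent simulator with Jukes-Cantor site evolution
    generates alignments with known species membership, and an
    orchestration layer runs the gene-order-randomised size-ladder scaling
    experiment, gene-by-gene comparisons, and Poisson regressions of
    species counts on gene informativeness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    phangorn,
    phytools,
    seqinr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
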