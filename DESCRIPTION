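Package: mitosig
Title: Neanderthal Signatures in Human Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative mitogenomics toolkit for screening modern human
    mitochondrial genomes for Neanderthal-shared single-nucleotide variants
    (N-SNVs). Anchors multiple alignments to the revised Cambridge Reference
    Sequence (rCRS), calls the polymorphic-site table, annotates variants
    against the mitochondrial gene map under the vertebrate mitochondrial
    genetic code, classifies Neanderthal-shared alleles into clade-presence
    patterns, dates variant sets under molecular-clock models, runs a
    sliding-window bootstrap (bootscan) recombination scan built on Kimura
    two-parameter distances and neighbor-joining trees, performs PCA of
    haploid genotype matrices, and ships a mitogenome-evolution simulator
    with rate heterogeneity, mutational hotspots and planted recombination
    for end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    phangorn,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
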