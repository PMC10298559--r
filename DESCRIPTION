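Package: tehorizon
Title: Horizontal Transfer Detection and Comparative Analysis of
    Transposable Element Loads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparative transposable-element (TE) genomics in
    groups of related species: parsing RepeatMasker annotations and
    consensus libraries, Kimura 2-parameter copy-divergence landscapes
    with molecular-clock dating, Nei-Gojobori synonymous-rate (dS)
    estimation for coding pairs, detection of horizontal TE transfer
    (HTT) by comparing TE-pair dS against the single-copy-ortholog dS
    null, clustering of HTT hits into a minimal set of transfer events,
    phylogenetic-signal statistics (Pagel's lambda, Blomberg's K),
    comparative model selection (BM, OU, EB, white noise) with ancestral
    reconstruction of TE loads, and a fully parameterised synthetic-data
    generator for end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
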