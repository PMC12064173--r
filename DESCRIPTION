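Package: psifold
Title: Differentiable RNA Folding and Gradient-Based Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the expected partition function of a distribution over
    RNA sequences under a nearest-neighbor thermodynamic model, together with
    exact gradients with respect to the per-position nucleotide probabilities.
    The dynamic program generalizes McCaskill's algorithm to a product of
    categorical distributions over nucleotides, uses per-nucleotide scaling to
    stay in floating-point range, and supports gradient checkpointing.
    Gradients drive inverse folding: design of sequences folding into a target
    secondary structure (directly over the sequence distribution or through an
    overparameterized generator network) and mRNA coding-sequence design
    trading off ensemble free energy against an expected codon adaptation
    index under a protein-coding constraint. Brute-force enumeration oracles
    over structures and sequences back the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tools,
    tibble,
    tidyr,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
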