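Package: lzphylo
Title: Alignment-Free Phylogenetics with Lempel-Ziv Relative Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free phylogeny reconstruction for unaligned
    nucleotide sequences. Computes Lempel-Ziv (LZ76) production
    complexity via the exhaustive-history parse, the relative complexity
    measure (RCM) pairwise distance derived from it, neighbor-joining
    trees, extended-majority-rule consensus trees with branch support
    counts, and Robinson-Foulds symmetric topology distances. Includes a
    pool-based perturbation resampler that conserves base composition
    for assessing tree robustness, and a sequence-evolution simulator
    (K2P and F84 substitution models, optional indels) for benchmarking
    reconstruction accuracy against a known true topology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    seqinr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
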