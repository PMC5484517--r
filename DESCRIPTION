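Package: phyloconflict
Title: Conflict Diagnostics for Phylogenomic Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Desk-scale tools for diagnosing conflicting phylogenetic signal in
    concatenated protein datasets: per-marker maximum-likelihood tree inference
    under LG+Gamma4 (Felsenstein pruning, NNI search, nonparametric bootstrap),
    approximately-unbiased topology testing via multiscale RELL bootstrap,
    BLOSUM-based alignment column trimming, chimeric-sequence screening
    (anchored-indel detection, donor attribution by local alignment,
    segment-affinity breakpoint scanning), concatenation ablation experiments
    (leave-one-marker-out, leave-one-sequence-out), and minimum-change analysis
    of gene fusion/fission characters with rooting scans. Ships a seeded
    simulator that generates marker sets evolved on conflicting species
    topologies with fast-evolving taxa and injected chimeras, together with
    machine-readable truth, so every diagnostic can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    Biostrings
Config/testthat/edition: 3
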