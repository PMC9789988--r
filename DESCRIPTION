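Package: ohnosel
Title: Selection, Synteny, and Expression Analysis of Duplicated Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of gene families retained from
    whole-genome duplications ("ohnologs"), motivated by the HIF-alpha gene
    family of ray-finned fishes. Implements a reversible Goldman-Yang codon
    substitution model with Felsenstein pruning likelihoods, one-ratio and
    two-ratio branch models with likelihood-ratio tests, site-level tests of
    pervasive and episodic positive selection (fixed-effects, mixed-effects,
    and ancestor-counting styles) plus a gene-wide branch-site random-effects
    test with per-site evidence ratios, synteny-based ohnolog naming rules
    (a/b after the teleost genome duplication, s1/s2 after the salmonid one),
    physicochemical profiling of selected sites via z-scale descriptors with
    k-means/BIC cluster selection and discriminant analysis of principal
    components, RPKM/TPM expression normalization with paralog-by-tissue
    median summaries, motif and domain mapping, and seeded synthetic-data
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
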