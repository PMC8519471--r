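Package: tirdesign
Title: Accessibility-Guided Design of Translation Initiation Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and redesigns the translation initiation region of
    protein-coding mRNAs by the opening energy (ensemble base-unpairing
    pseudo-energy) of start-codon-anchored regions. Provides a pluggable
    secondary-structure engine (ViennaRNA subprocess or an exactly testable
    toy partition-function model), simulated-annealing synonymous-codon
    optimization of the first N codons with restriction-site avoidance,
    competing codon-usage features (CAI, tAI, codon context, G+C,
    ncRNA-avoidance hybridization energy), a likelihood-ratio based
    Expression Score built from ROC analysis, bootstrap confidence
    intervals and a four-parameter logistic fit, and a stochastic simulator
    of recombinant protein production and cell growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
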