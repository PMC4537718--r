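Package: fethmm
Title: Spatially Enhanced Differential RNA Methylation Analysis from
    MeRIP-Seq Bin Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially methylated regions within m6A MeRIP-Seq
    methylation sites at bin resolution. Each site is divided into ordered
    adjacent bins; per-bin significance of differential methylation between
    two conditions is assessed with a library-rescaled two-tailed Fisher's
    exact (hypergeometric) test, and spatial dependency between adjacent
    bins is incorporated with a two-state hidden Markov model under three
    strategies: binary-observation Baum-Welch (FHB), p-value-derived fixed
    emissions with EM on the initial and transition parameters (FHC), and a
    fast single-pass pooled-parameter E-step variant (FastFHC). Includes a
    Poisson count simulator with Markov-dependent ground-truth states and
    bin-level ROC/AUC benchmarking harnesses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
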