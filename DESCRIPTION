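Package: admixpaint
Title: Local Ancestry Inference in Admixed Genomes via a Two-Layer
    Haplotype-Copying HMM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers fine-scale local-ancestry segments in admixed genomes
    without requiring that reference panels be direct surrogates for the
    mixing groups. A two-layer haplotype-copying hidden Markov model jointly
    tracks the latent ancestry and the donor haplotype being copied at each
    point of an even genetic-distance grid; the panel-to-ancestry copying
    matrix, ancestry-switch rates, haplotype-switch rate and miscopying rate
    are learned by Baum-Welch EM. Includes donor thinning via an
    ancestry-unaware painting pass, hill-climbing correction of statistical
    phasing errors, admixture dating by exponential-decay coancestry curves
    with chromosome bootstrap, drift summaries (Weir-Cockerham-style Fst,
    Rst, expected coefficient of determination), a mean-ancestry selection
    scan, and a synthetic admixture simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
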