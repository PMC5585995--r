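Package: macaller
Title: Probabilistic Mutation Calling and Rate Estimation for Mutation
    Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects de novo base-substitution mutations in mutation
    accumulation (MA) experiments from per-site stranded base counts. A
    Dirichlet-multinomial genotype-likelihood model with an F81
    nucleotide-substitution transition marginalizes exactly over the hidden
    histories of an MA experiment (ancestral diploid genotype, allele
    transmission through genomic exclusion, descendant outcomes) to give
    per-site posterior mutation probabilities that are robust to
    overdispersed sequencing noise. Also provides a count-level consensus
    co-caller, a shuffled-read-count estimator of callable sites, per-site
    per-generation mutation-rate estimation with normal, log-space and
    exact Poisson confidence intervals, a generative simulator for the full
    model, tally/mpileup input handling, diagnostic summaries and plots,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    graphics,
    optparse,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
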