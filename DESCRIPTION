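Package: glyrfluct
Title: Fluctuation Analysis of Glycinergic Whole-Cell Currents
Version: 0.1.0
Authors@R:
    person("glyrfluct", "developers", email = "glyrfluct@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of glycinergic (glycine receptor mediated)
    whole-cell currents and related assays: template-matched detection and
    kinetic measurement of miniature inhibitory postsynaptic currents,
    stationary noise (variance-mean) analysis yielding unitary current,
    channel number and open probability, Lorentzian power-spectrum analysis
    of channel gating, Hill dose-response EC50 estimation, tonic-inhibition
    quantification against an antagonist step, contingency statistics for
    behavioural phenotype tables, and in-silico restriction-digest
    genotyping. Ships a seeded synthetic-data generator (exact two-state
    Markov channel ensembles, Poisson trains of biexponential events,
    dose-response tables) with recorded ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    rhdf5,
    withr
Config/testthat/edition: 3
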