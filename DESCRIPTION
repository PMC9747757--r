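Package: quasicrit
Title: Neuronal Avalanches, Effective Exponents and Quasicriticality Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying quasicritical dynamics in multichannel neural
    recordings. Provides a probabilistic cellular-automaton simulator of the
    cortical branching model (random directed networks with exponentially
    biased inbound weights, a branching parameter, spontaneous activation and
    refractoriness), event extraction from continuous signals by z-score
    thresholding and time binning, neuronal-avalanche statistics with discrete
    power-law exponent fits, the gamma-scaling-line position biomarker,
    dynamical susceptibility and related activity statistics including naive
    and multistep-regression branching-ratio estimators, and a synthetic
    MEG-like cohort generator that makes the full age-trend pipeline testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
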