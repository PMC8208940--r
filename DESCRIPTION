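Package: lvoc
Title: Learned Value of Control Modeling for Rewarded Stroop Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate, simulate, and analyze a two-phase rewarded
    Stroop choice experiment in which participants freely choose between
    color naming (control-demanding) and word reading (automatic).
    Implements the Learned Value of Control (LVOC) agent -- Bayesian linear
    regression over stimulus features with Thompson sampling of a control
    signal, coupled to a two-boundary drift-diffusion response process --
    along with condition-level diffusion-model fitting (maximum likelihood
    and random-walk Metropolis), simulation-based likelihood fitting of the
    LVOC parameters, comparator models (win-stay-lose-shift and a
    Rescorla-Wagner stimulus-response learner with exponentiated Luce
    choice), BIC model comparison, and model-free behavioral summaries
    (goal-inconsistent response rates, reward rate, moving averages).
    Reproduces feature-based maltransfer: graded overexertion of cognitive
    control on stimuli whose component features were individually rewarded
    for control under an XOR transfer rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
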