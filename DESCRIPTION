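Package: ewspec
Title: Spectral Early Warning Signals for Tipping Points
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and distinguishes approaching tipping points in univariate
    time series using spectral early warning signals. Provides closed-form
    variance, lag autocorrelation and power-spectrum approximations for every
    local codimension-1 bifurcation (Fold, Transcritical, Pitchfork, Hopf,
    Flip, Neimark-Sacker) obtained from Ornstein-Uhlenbeck theory; the S_max
    spectral-peak indicator and an AIC-weight classifier that discriminates
    oscillatory from non-oscillatory bifurcations by fitting canonical spectral
    forms; stochastic simulators for bifurcation normal forms and a harvested
    Ricker population model; a detrending / rolling-window / stationary
    block-bootstrap pipeline with Kendall tau trend statistics; and ROC/AUC
    evaluation of indicators on ensembles of forced and null simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
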