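Package: tempogate
Title: Stochastic Modelling and Event Inference for a Two-Integrase Temporal Logic Gate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a serine-integrase temporal logic gate as a
    continuous-time Markov chain over DNA cassette states and integrase
    copy numbers, using an exact stochastic simulation algorithm with
    piecewise-constant induction schedules. Provides a truncated
    chemical-master-equation oracle for validation, population-level
    analysis of state-fraction time courses and inducer-separation scans,
    mean-squared-error grid calibration of flipping rates, inversion of
    measured fluorescent population fractions into pulse width and
    inducer separation time, and a synthetic-data generator emulating
    flow-cytometry measurements of engineered cell populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
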