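Package: swinepk
Title: Population Pharmacokinetics of Carprofen in Swine
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Complete pharmacokinetic workflow for carprofen given
    intravenously and intramuscularly to pigs in a crossover design:
    closed-form two-compartment disposition with first-order absorption,
    a synthetic-study generator with log-normal between-animal variability
    and proportional residual error, non-compartmental analysis
    (lambda-z regression, linear/log trapezoidal areas, statistical
    moments), nonlinear mixed-effects estimation by stochastic
    approximation EM with a Laplace fallback, visual predictive checks and
    nonparametric bootstrap, multiple-dose regimen simulation against a
    therapeutic window, and LC-MS/MS bioanalytical validation statistics
    including an exact Mann-Whitney test for tissue residues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
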