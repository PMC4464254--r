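Package: riskdeck
Title: Risk-Preference Modelling and Synthetic Neuroimaging Analysis for a
    Four-Deck Probabilistic Card Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a four-deck probabilistic card task in
    which each deck shows a card value and pays off when a hidden second card
    is lower.  Implements a mean-variance utility model with softmax choice,
    maximum-likelihood estimation of an individual risk-preference weight,
    goodness-of-fit comparison against uniform-random agents (per-trial
    negative log-likelihood, AIC, AICc, BIC), Shannon-entropy choice
    difficulty, parametric-modulation GLM regressor construction with a gamma
    haemodynamic response, resting-state functional-connectivity cleaning
    (motion regression, framewise-displacement scrubbing, band-pass
    filtering, nuisance regression, Fisher z), and group-level correlation,
    partial-correlation and Sobel mediation statistics.  A synthetic-cohort
    generator produces behavioural, task-BOLD and resting-state data with
    known ground truth so the full pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
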