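Package: pavbias
Title: Intertemporal Pavlovian Bias Modelling for Go/No-Go Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of intertemporal go/no-go
    learning tasks in which the timing (immediate versus delayed) of a
    preference-matched monetary reward is orthogonalized against the required
    instrumental action. Provides pseudorandom task-schedule generation with
    probabilistic feedback, an adaptive delay-discounting choice-titration
    procedure with monetary-choice-questionnaire scoring, a family of six
    nested Rescorla-Wagner reinforcement-learning models (go bias, irreducible
    noise, Pavlovian cue-response bias, and outcome-contingent learning bias),
    per-participant maximum a posteriori estimation via box-constrained
    differential evolution, AIC-based model comparison, parameter and model
    recovery, posterior predictive checks, hierarchical response-bias and
    shifted-lognormal response-time regressions with Benjamini-Hochberg
    multiplicity control, and a synthetic-cohort generator with known ground
    truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    lme4,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
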