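Package: hydrostatus
Title: Dehydration Classification from Wearable Orthostatic Heart-Rate Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating mild exercise-induced dehydration (>= 2%
    bodyweight loss) from wearable heart-rate and trunk-pitch recordings of
    scripted postural movements. Provides a synthetic cohort simulator for
    paired heart-rate and inertial pitch streams, automatic postural-transition
    detection from pitch velocity, baseline-relative segmented heart-rate
    features, L2-regularized logistic regression with leave-one-participant-out
    evaluation, AUROC summaries with interquartile ranges, and exact Shapley
    feature attribution with AUROC as the value function.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
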