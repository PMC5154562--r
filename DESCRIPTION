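Package: squatcrf
Title: Cardiorespiratory Fitness Estimation from the 45-Second Squat Self-Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maximal oxygen uptake (VO2max) from heart-rate
    inter-beat intervals recorded around a 45-second squat self-test.
    Provides RR-interval cleaning (despiking and moving-average smoothing),
    extraction of rest, squat and recovery heart-rate features including the
    Ruffier-Dickson Index and linear/exponential recovery-curve fits, three
    published multiple-regression prediction equations, de-novo stepwise
    model refitting, and a validation battery: leave-one-out
    cross-validation, Bland-Altman agreement, intraclass correlation,
    three-class fitness classification with sensitivity, specificity and
    Cohen's kappa, and a training-size stability simulation. A synthetic
    cohort and trace generator makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, minpack.lm, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
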