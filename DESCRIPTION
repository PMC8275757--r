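Package: pupilcontrol
Title: Pupillometry Pipeline for Quantifying Self-Regulation via the Pupil Dilation Index
Version: 0.1.0
Authors@R: person("pupilcontrol", "developers", role = c("aut", "cre"),
    email = "maintainers@pupilcontrol.invalid")
Description: Tools for event-locked pupillometry analyses of self-control
    experiments: blink/loss-mask widening and linear interpolation, within-run
    z-scoring, trial epoching with pre-stimulus baseline correction, the
    Reappraise>View contrast, a max-cluster sign-flip permutation test, the
    Pupil Dilation Index (PDI), emotion-regulation and dietary-choice outcome
    scores, flat-prior Bayesian (and OLS) regression with JZS Bayes factors,
    Bayesian rank correlation, leave-two-participants-out pairwise prediction
    with a permutation null, and a fully parameterised synthetic-cohort
    generator for end-to-end testing without any raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
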