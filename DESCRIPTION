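Package: dyadsync
Title: Dyadic Cardiac Synchrony and Heart Rate Variability Pipelines
Version: 0.1.0
Authors@R:
    person("dyadsync", "maintainers", email = "maintainers@dyadsync.org",
           role = c("aut", "cre"))
Description: Tools for studying interpersonal cardiac physiology in small
    group interactions. Provides artifact correction and uniform resampling
    of beat-to-beat (R-R) interval recordings, windowed high-frequency heart
    rate variability, Morlet cross-wavelet power synchrony between paired
    heart-rate trajectories with band-wise interval maxima and pooled
    z-scoring, questionnaire-derived dyadic measures (affect coherence,
    empathic accuracy, friendship status, closeness and liking aggregates),
    multilevel models with AR(1) residuals for repeated dyadic outcomes, and
    a fully seeded synthetic cohort generator with planted coupling effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
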