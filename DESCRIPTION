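Package: qpass
Title: Multifactorial Quality Scoring of Basketball Passes from Arm-Worn Gyroscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the Q-Pass index, a 0-100 multifactorial quality score
    for basketball passes that combines pass accuracy, execution time and
    movement-pattern variability measured with two gyroscopes worn on the
    dominant arm (wrist and humerus). Provides kinematic primitives for
    two-sensor angular-velocity streams (vector-sum magnitudes, zero-phase
    Butterworth low-pass filtering, rectangle-rule integration over annotated
    pass windows), the penalty framework with cohort references and
    max-to-100 normalization, configurable factor weighting, reliability
    statistics (SEM from repeated-measures ANOVA, coefficient of variation),
    group comparisons (Student's t, Hedge's g), and a seeded generator of
    synthetic two-sensor recordings emulating a two-group passing-test
    cohort, so the full pipeline is testable without access to raw
    recordings.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
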