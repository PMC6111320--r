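Package: stressmark
Title: Multimodal Biosignal Stress Markers and Three-Level Stress Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting mental stress from simultaneously
    recorded physiological signals (four-channel frontal EEG, ECG, differential
    trapezius EMG, and galvanic skin response). Implements zero-phase Butterworth
    preprocessing, four per-epoch stress markers (relative gamma band-power
    ratio, heart rate from R-peak detection, MVC-normalized trapezius activity,
    and skin conductance), grand-average statistics with paired t-tests and
    Fisher-transform Pearson confidence intervals, and three-level (stress,
    relax, neutral) linear discriminant classification under leave-one-epoch-out
    and leave-one-subject-out cross-validation. Includes a synthetic-session
    generator that emulates the stress-induction protocol (rest, mental
    arithmetic stressor, relaxation, rest) so every stage is testable without
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
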