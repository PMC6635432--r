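Package: cyclehmm
Title: Menstrual Cycle Phase Segmentation and Ovulation Estimation from
    Sympto-Thermal Self-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily self-tracked fertility-awareness
    observations (basal body temperature, cervical mucus, bleeding, cervix
    position, vaginal sensation) from mobile cycle-tracking apps. Provides a
    canonical data model with readers for two app dialects (Sympto, Kindara),
    a synthetic-cohort generator with known ground truth, cycle-quality
    filtering, per-cycle-day descriptive profiles, a ten-state hidden Markov
    model of the hormonal events of the menstrual cycle with Viterbi and
    forward-backward decoding under missing data, ovulation-day estimation
    with uncertainty and confidence indicators and a reliability gate, and
    cohort-level summary tables of cycle and phase durations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
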