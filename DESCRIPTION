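Package: dstsim
Title: Simulation Engine and Statistical Evaluation for a Smartphone Digital Stress Test
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, seeded simulation engine for a smartphone-delivered
    acute psychosocial stress protocol (the Digital Stress Test and its
    non-stressful control variant): adaptive-staircase mental arithmetic with
    keypad swapping and a rescue rule, a timed free-speech task with silence
    reminders, and event-logged sessions. Includes a synthetic-participant and
    cohort generator (skill, affect and dropout models), scoring of the
    I-PANAS-SF and visual analogue scale instruments, and the complete
    statistical evaluation pipeline: assumption checks, mixed-design ANOVA
    with Greenhouse-Geisser correction and partial eta squared,
    Bonferroni-adjusted Welch post hoc tests, paired t tests, two Cohen's d
    variants for pre/post change, and a two-step inverse-variance
    meta-analysis of standardized affect changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
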