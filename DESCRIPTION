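Package: hmadapt
Title: Hierarchical Motor Adaptation Models for Force-Field Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for trial-by-trial arm-reaching
    adaptation to force fields that do or do not induce target errors.
    Implements a point-mass optimal feedback control (LQG-style) learner and a
    two-joint six-muscle V-shaped (feedback-error) learner, each in a flat
    (internal-model-only) and a hierarchical variant in which a failure-driven
    kinematic plan (aim-direction bias or via-point deflection of a
    minimum-jerk desired trajectory) is updated by target error and gated by
    motor cost. Provides the behavioral metrics (target error, lateral
    deviation, y-grid resampling, epoch summaries, exclusion and screening
    rules), the reported statistics (summary-statistic t tests,
    Greenhouse-Geisser-corrected repeated-measures ANOVA with partial eta
    squared, Tukey and Bonferroni procedures), a seeded synthetic
    multi-participant dataset generator, and retention/sensitivity parameter
    recovery for the trial-to-trial update rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
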