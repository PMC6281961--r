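Package: hapticforce
Title: Simulation and Analysis of Indentation Forces in Active Haptic
    Softness Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people tune their finger indentation
    forces while exploring the softness of deformable objects.  The package
    builds fully counterbalanced two-alternative forced-choice (2AFC)
    discrimination schedules for compliance-defined stimuli, simulates
    force/position recordings of repeated indentation with planted
    predictive, sensory and motivational force adjustments, extracts peak
    indentation forces from force traces (moving-average smoothing,
    derivative sign-change peak detection with a refractory interval), and
    runs the repeated-measures analysis battery: linear contrast tests on
    difference scores, paired t tests, coefficient-of-variation convergence,
    rationalized arcsine transforms of accuracy, Cousineau-Morey
    within-participant standard errors, and composite motivation scoring
    with social-desirability residual correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
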