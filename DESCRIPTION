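Package: divekin
Title: Kinematic and Kinetic Analysis of Soccer Goalkeeper Penalty Dives
Version: 0.1.0
Authors@R:
    person("divekin", "developers", email = "divekin@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for analysing soccer goalkeepers'
    penalty diving saves from centre-of-mass (CM) trajectories and
    force-plate recordings. Provides a mechanistic synthetic-dive
    generator with exact analytic ground truth, zero-lag Butterworth
    filtering with residual-analysis cutoff selection, detection of the
    dive window (CM vertical minimum to maximum) and of the push-off
    impulse phase, computation of 14 displacement, velocity,
    weight-normalised peak-force and impulse outcome variables, and the
    paired statistical comparisons (old vs new goalkeeper feet-positioning
    rule, lower-limb laterality, and rule within side) with Shapiro-Wilk
    checks, paired t-tests and Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
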