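Package: motorskill
Title: Skill Learning Analysis for Force-Control Motor Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sequential isometric pinch-force
    skill-learning experiments: converts trial-level records into per-block
    speed-accuracy skill scores, estimates group learning rates by robust
    (iteratively reweighted least squares) regression of skill on practice
    block, and tests group differences in learning rate by subject-level
    permutation of the slope difference. Also provides mixed-design
    repeated-measures ANOVA with Greenhouse-Geisser correction, maximal
    voluntary contraction and time-to-fatigue quantification from force
    traces, an error decomposition by force gate and direction, and a
    synthetic-data generator that emulates the behavioural structure of
    fatigue/skill-learning experiments so every analysis stage is testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    MASS,
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
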