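Package: manipkin
Title: Kinetics and Kinematics of Prone Cervical HVLA Manipulation Trials
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify prone stretching-and-adjusting neck
    manipulation (a high-velocity low-amplitude cervical technique) from
    synchronized motion-capture marker trajectories and dual force-plate
    recordings. Segments the vertical ground-reaction-force curve into
    stretching, triggering and return phases (turning points A/B/C/D),
    extracts baseline-referenced loaded-force peaks, detects the mid-trial
    subject position-change artifact, estimates head and thorax rigid-body
    poses by orthogonal Procrustes (Kabsch) fits, computes the head-on-thorax
    axial rotation angle, the operator trigger time from acromion
    displacement, and the neck extension amplitude. Includes a synthetic
    trial generator with full ground truth, cohort-level statistics
    (Shapiro-Wilk, Levene, paired t), C3D and CSV trial I/O, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
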