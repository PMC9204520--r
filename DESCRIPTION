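Package: squatmc
Title: Monte Carlo Uncertainty Propagation for Knee Contact Force
    Estimates During Squat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale musculoskeletal simulation pipeline for studying how
    uncertainty in muscle-tendon parameters (maximum isometric force, tendon
    slack length, pennation angle, and muscle pathway points) propagates to
    knee contact force estimates during body-weight squat.  Provides a reduced
    sagittal-plane lower-limb model with Hill-type muscle mechanics and
    tendon-excursion moment arms, inverse kinematics and quasi-static inverse
    dynamics, per-frame static optimization of the muscle redundancy problem,
    joint reaction force assembly, Gaussian parameter-perturbation Monte Carlo
    designs with a convergence check, percentile-band and contribution-factor
    statistics, an EMG conditioning chain, and a synthetic-data generator for
    subjects, squat trials, ground-truth contact forces, and EMG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
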