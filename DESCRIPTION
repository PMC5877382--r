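Package: equigait
Title: IMU-Based Equine Gait Analysis with Optical Motion Capture Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for equine gait analysis from body-mounted
    inertial measurement units (IMUs): complementary-filter orientation
    estimation, swing-twist limb angle extraction from cannon-bone sensors,
    cyclic double integration of upper-body acceleration to vertical
    displacement, and per-stride movement-symmetry parameters. Includes
    data-driven time synchronization and Kabsch rotational alignment against an
    optical motion capture (OMC) reference stream, agreement statistics
    (Bland-Altman limits of agreement with repeated-measures confidence
    intervals, intra-class correlation from a random-intercept model), and a
    seeded kinematic gait simulator that provides ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
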