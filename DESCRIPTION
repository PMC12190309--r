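Package: gaitcoord
Title: Hip-Knee Coordination Analysis from Wearable IMU Gait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying sagittal-plane hip-knee
    inter-joint coordination from body-worn inertial measurement units (IMUs)
    in older adults with and without Parkinson's disease. Raw tri-axial
    accelerometer, gyroscope and magnetometer streams are fused to unit
    quaternions with a complementary filter, converted to sagittal hip and
    knee joint angles via an intrinsic Z-Y-X Euler decomposition, segmented
    into gait cycles from shank angular velocity, and summarized with
    continuous relative phase (CRP) via the Hilbert transform, Mean Absolute
    Relative Phase (MARP), Deviation Phase (DP) and joint excursion.
    Group-level inference includes Tukey-fence outlier exclusion, two-way
    ANOVA/ANCOVA with a walking-speed covariate and Bonferroni post hocs, and
    permutation-based one-dimensional statistical parametric mapping (SPM)
    over the gait cycle. A calibrated synthetic gait-cohort generator with
    known ground truth supports validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
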