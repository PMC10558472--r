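Package: mwaplan
Title: Model-Based Microwave Ablation Planning with Hepatic Vessel Heat-Sink Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates percutaneous microwave ablation of liver tissue by solving the
    Pennes bioheat equation on a regular voxel grid with a temperature- and
    damage-dependent perfusion sink, a fifty-fold perfusion enhancement on segmented
    vasculature, tissue water evaporation through an effective heat capacity, a
    calibrated simplified applicator heat source, and Arrhenius thermal damage.
    Includes synthetic liver/vessel phantom generation (bifurcating Murray-law vessel
    trees, ground-truth distortion, misalignment and infarction-wedge artifacts),
    segmentation validation metrics (Dice overlap, signed surface distance with
    absolute-average-error aggregation, vascular fraction), and cohort-level
    statistics (identity-line deviation, Tukey range test, exclusion criteria,
    whisker summaries) for retrospective replay of treatment-planning validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
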