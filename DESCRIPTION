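Package: arithmvpa
Title: Simulation and Multivoxel Pattern Analysis of Arithmetic fMRI in
    Dyslexia and Dyscalculia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse block-design arithmetic fMRI
    studies of children with developmental dyslexia, dyscalculia, or both.
    Provides a synthetic-cohort generator (task designs, head-motion traces,
    4D BOLD runs with latent group-structured activation patterns, and
    behavioural tables), head-motion quality control with run- and
    subject-level exclusion rules, first-level boxcar GLM contrast
    estimation with motion nuisance regressors, voxelwise 2x2 factorial
    group ANOVA with false-discovery-rate correction, leave-pair-out
    cross-validated subject classification with Monte-Carlo permutation
    significance cutoffs, a bidirectional cross-disorder subject
    generalization test, and mixed-design behavioural ANOVAs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    car,
    e1071,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
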