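Package: xerosubvol
Title: Regional Salivary-Gland Dose Patterns for Xerostomia Injury and Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the regional distribution of radiotherapy dose
    across salivary-gland subvolumes relates to xerostomia injury and recovery
    in head-and-neck cancer. Partitions parotid, submandibular and oral-cavity
    structures into 22 named subvolumes (3 mm expansion shells, superior-
    inferior thirds, equal-angle radial sectors, a geometric oral-cavity
    surrogate), extracts D10-D90 dose-volume-histogram features, screens
    features with single-step max-T permutation tests, and fits ridge-penalized
    logistic models with nested cross-validation and normalized importance
    maps. Includes a fully synthetic cohort generator (ellipsoidal anatomy,
    Gaussian dose fields, logistic outcome mechanism, longitudinal CTCAE
    timelines) so every stage can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
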