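Package: icedecomp
Title: Variance-Component Decomposition of Scan-Rescan Reliability for
    Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes repeated quantitative-MRI measurements into
    true-score, day-specific, session-specific, and residual variance
    using maximum-likelihood estimation of a structured covariance model
    (intra-class effect decomposition, ICED), yielding ICC and
    construct-level ICC2 reliability coefficients, likelihood-ratio and
    Wald tests for the individual variance components, RMSEA model-fit
    statistics, and bootstrap confidence intervals. Includes voxel-wise
    reliability mapping for NIfTI volumes, coefficient-of-variation
    summaries, multi-echo R2* estimation by joint log-linear (ESTATICS)
    fitting, Ernst-equation signal modelling with dual-flip-angle R1
    recovery, proton-density white-matter calibration, and seeded
    synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
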