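Package: alffcn
Title: Functional Covariance Networks from Low-Frequency Fluctuation Amplitudes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates resting-state brain networks from the across-subject
    covariance of the amplitude of low-frequency fluctuations (ALFF), alongside
    two comparator estimators: within-subject time-series intrinsic connectivity
    networks and gray-matter structural covariance networks. Includes band-pass
    filtering and Gaussian smoothing of 4D BOLD volumes, voxel-wise ALFF with
    global-mean standardization, seed-based general linear models with nuisance
    covariates, Bonferroni family-wise-error thresholding, connected-component
    cluster tables, hierarchical clustering of network maps, sign-aware
    conjunction analysis, the two-system dichotomy statistic, a synthetic
    multi-subject cohort generator with planted ground truth, and a study
    pipeline with a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
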