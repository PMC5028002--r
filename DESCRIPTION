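Package: corticomap
Title: Structural and Functional Mapping of the Cortical V5/MT Complex
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the alignment of structural (myelin-weighted
    structural MRI) and functional (motion-localizer fMRI and phase-encoded
    retinotopy) definitions of the V5/MT-MST cortical complex, together with
    a histological validation arm. Provides minimal NIfTI-1 and GIFTI
    readers/writers, cortical-depth sampling of volumes onto triangulated
    surfaces, quantile and mean-plus-k-SEM thresholding into heavily
    myelinated masks, contiguous-region surface-area measurement, z-statistic
    cluster extraction with permutation-calibrated extent thresholds, Fourier
    analysis of phase-encoded retinotopy with a coherence criterion, areal
    overlap and correspondence statistics with intensity-shuffle permutation
    nulls, threshold-sensitivity sweeps, histological myeloarchitecture
    profiles and section-series area estimation, and a synthetic cortical
    phantom generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, jsonlite, xml2
Suggests: testthat (>= 3.0.0), png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
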