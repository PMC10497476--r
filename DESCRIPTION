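Package: patlakpet
Title: Patlak Parametric Imaging and Framing-Protocol Evaluation for Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for oncological Patlak graphical analysis of 60-minute
    dynamic 18F-FDG PET. Provides frame-schedule handling for six standard
    framing protocols (100 to 12 frames), rebinning of dynamic images and
    time-activity curves between protocols, image-derived input function
    extraction from a cylindrical descending-aorta ROI, ROI-level and
    vectorized voxelwise Patlak fitting (Ki, intercept, SSE maps), and the
    protocol-comparison machinery (relative differences, Bland-Altman,
    correlation, paired t-test, variance F-test). A synthetic dynamic-PET
    phantom (tri-exponential arterial bolus, two-tissue irreversible tissue
    kinetics, count-like noise) makes the full workflow testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
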