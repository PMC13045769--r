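Package: spmkit
Title: Filtering, Segmentation and Drift Correction for Scanning-Probe
    Microscopy Image Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for semi-quantitative analysis of scanning tunnelling
    microscopy (STM) image series: reading and writing XYZ ASCII topographs
    and a minimal binary raw-scan dialect, line-wise parabolic background
    subtraction (flattening), percentile-based contrast equalisation with
    zero rebasing, segmentation of per-image Z-value distributions by
    univariate Gaussian mixture models or by fixed equal-width thresholds
    calibrated on the first frames of a series, anchor-based correction of
    slow translational drift across long image sequences, and a synthetic
    molecular-monolayer generator with full ground truth for offline
    validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    png,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
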