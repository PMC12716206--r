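Package: PartialScan
Title: Line-Skipping Acquisition and Mask-Aware Image Reconstruction for
    Scanning Ion Conductance Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Partial-Scan approach to scanning ion conductance
    microscopy (SICM): generate per-line scan masks (random, run-limited and
    patterned), derive the modified slow-axis scan waveform, simulate partial
    acquisition of topography height maps, and reconstruct the skipped lines
    with a mask-aware partial-convolution encoder-decoder trained with a
    combined SSIM and mean-squared-error loss. Includes non-learned baselines
    (column-wise linear interpolation, median line correction), a synthetic
    SICM-like cell topography generator, a full image-quality metric suite
    (MSE, PSNR, SSIM, Pearson correlation, Canny edge density and
    high-frequency content ratio), masking-fraction sweeps with three-segment
    piecewise-linear break-point regression, and scan-line artifact (scar)
    detection and correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
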