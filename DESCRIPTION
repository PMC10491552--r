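Package: us3dqa
Title: Image-Quality Analysis for Motorized and Freehand 3D Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multi-purpose ultrasound calibration phantom acquired
    either by a motorized stepper sweep or by a tremor-affected, electromagnetically
    tracked freehand sweep; reconstructs 3D volumes by slice stacking or by
    temporally calibrated pixel-nearest-neighbour gridding with maximum-value
    compounding; and computes phantom-based image-quality metrics (contrast
    resolution slope, -6 dB full width at half maximum, distance-calibration
    error, and a surface-stability statistic) together with the comparison
    statistics used for acquisition-protocol studies (paired t-tests and
    two-way absolute-agreement intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
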