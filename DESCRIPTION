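Package: phscreen
Title: Ratiometric pH-Biosensor Imaging, Calibration and Colony Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-excitation ratiometric pH biosensors
    (mCherryEA-type) in bacterial colonies and liquid cultures. Simulates
    sensor-bearing colonies on agar plates and kinetic plate-reader assays
    with known ground truth, quantifies arrayed colonies in two-channel
    16-bit plate images, fits a Boltzmann sigmoid calibration, inverts
    fluorescence ratios to internal pH with detection-limit clamping, and
    calls screening hits by robust z-score. Includes CTAB-permeabilization
    recalibration of kinetic series and first-order pH-homeostasis models
    for strain phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
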