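Package: cardioscreen
Title: Automated Zebrafish Cardiodynamics and High-Content Fluorescence Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies larval zebrafish cardiac function from fluorescence
    time-lapse microscopy. Segments the beating ventricle by intensity
    thresholding with hole filling and a minimum-area rule, converts
    cross-sectional area to chamber volume through a prolate-spheroid
    calibration fitted on arrested hearts, and estimates stroke volume, heart
    rate, cardiac output and ejection fraction with a pure frequency-domain
    (Tukey-windowed FFT) method and a combined frequency/time-domain
    (segmentation) method, cross-checked against a manual peak-trough
    reference. Includes a synthetic-data generator (cardiac waveforms,
    rendered ellipsoidal frame stacks, calibration pairs, well-plate image
    sets) and well-plate acquisition planning and per-well fluorescence
    quantification for high-content screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
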