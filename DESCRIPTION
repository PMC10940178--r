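Package: mriecg
Title: Quantifying 12-Lead ECG Distortion in the MRI Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how the static magnetic field of an MRI
    scanner distorts the 12-lead electrocardiogram. Provides a synthetic
    12-lead ECG generator with a magnetohydrodynamic (MHD) artifact model
    tied to aortic flow, a beat detection, template classification and
    aligned averaging pipeline, a multi-stage beat-comparison error metric
    with interval-wise summaries, ST-deviation and contiguous-lead ischemia
    assessment, agreement and rank-based statistics, and waveform and
    annotation file input and output with a study-level driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
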