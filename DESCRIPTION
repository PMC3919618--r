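Package: telogel
Title: Telomere Length Measurement from Terminal Restriction Fragment Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Densitometric analysis of terminal restriction fragment (TRF)
    Southern blots for telomere length measurement. Provides raw-preserving
    TIFF import of gel scans, automatic lane detection by Otsu thresholding
    and x-projection minima, molecular-weight ladder calibration with four
    selectable monotone fit models scored by adjusted R-squared, per-lane
    intensity profile extraction with background subtraction, Gaussian smear
    modelling by iterative least squares, probe-intensity bias correction
    based on mirroring the rising (low molecular weight) flank of the smear,
    per-lane summary statistics and reports, and a ground-truthed synthetic
    gel generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
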