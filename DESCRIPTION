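Package: atmbeat
Title: Automated Template Matching for Arrhythmia Recognition in
    Cardiomyocyte Impedance Beating Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing hERG-inhibitor-induced arrhythmia in
    impedance-based cardiomyocyte mechanical beating recordings by automated
    template matching (ATM). Implements the full signal chain: FFT amplitude
    demodulation of the 10 kHz carrier, 5-point smoothing, cubic-spline
    upsampling from 12.8 ms to 1.28 ms resolution, adaptive-threshold valley
    detection and beat extraction, dynamic template length matching by spline
    interpolation and resampling, Pearson-correlation classification against
    rhythmic and arrhythmic beat templates with calibrated thresholds, and
    recognition-accuracy evaluation. Ships a synthetic beating-signal
    simulator with per-beat ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
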