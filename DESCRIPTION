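Package: stepcountr
Title: State-Adaptive Step Counting from Tri-Axial Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Counts steps in tri-axial accelerometer recordings using an
    adaptive peak-detection pipeline: orientation-free RMS magnitude with a
    zero-phase 3 Hz low-pass filter, walking-state classification (slow,
    normal, fast) from windowed mean magnitude, candidate peak detection
    under state-specific minimal peak distance, minimal peak prominence,
    dynamic mid-range thresholding, and vibration elimination, followed by
    step confirmation through periodicity and same-leg amplitude similarity.
    Includes a parametric synthetic gait generator with ground-truth step
    times for end-to-end verification, two baseline counters for method
    comparison, CSV input/output for recordings and step annotations, and
    error/accuracy evaluation against true counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
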