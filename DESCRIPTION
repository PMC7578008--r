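Package: pulsemag
Title: Contactless Heart-Rate Tracking from Face Video by Eulerian
    Video Magnification and Wavelet Ridge Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-pass video photoplethysmography pipeline for primate (and
    human) face video. Sub-percent cardiac luminance fluctuations in a skin
    region of interest are amplified by Eulerian video magnification
    (Gaussian pyramid, ideal temporal band-pass), heart rate is extracted as
    the peak-frequency ridge of a complex Morlet wavelet transform of the
    pixel-averaged trace, and the band is refined around the first-pass
    estimate for a second magnification round. Includes ECG R-peak detection
    for ground truth, wavelet-coherence validation of the video-derived rate
    against ECG, a spatial region-of-interest coherence map, peristimulus
    heart-rate-change statistics (Wilcoxon tests, Cohen's d against run
    variability), and a fully synthetic paired video + ECG + event generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
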