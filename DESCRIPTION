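Package: wearsig
Title: Preprocessing and Clinical Feature Extraction for Smartwatch Health Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Signal-processing pipeline for daily health streams exported from
    wrist-worn wearables (heart rate, beat-to-beat intervals, pulse oximetry,
    respiration rate, steps and calories). Irregular streams are retimed onto a
    uniform grid by nearest-grid-point averaging, bounded gaps are filled by
    linear interpolation under per-signal duration limits, and noise is removed
    with a centred moving average. From the cleaned signals the package extracts
    the full clinically motivated feature catalogue: time-domain and geometric
    heart-rate-variability indices (Poincare SD1/SD2, asymmetry and
    fragmentation measures), nocturnal oxygen-desaturation metrics (ODI, CT,
    CA, AOD), and breath-to-breath interval features including Welch band
    powers, approximate and sample entropy, and (multifractal) detrended
    fluctuation analysis. Seeded synthetic-data generators with ground truth
    support end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
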