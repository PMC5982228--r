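Package: ltmbeat
Title: Multilead R-Wave Detection for Long-Term ECG Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Beat-by-beat QRS (R-wave) detection for long-term multilead
    ECG (Holter) recordings. Implements a segmented processing pipeline:
    baseline detrending, powerline notch and low-pass filtering,
    variance-based motion-artifact suppression, Pan-Tompkins-style
    feature signals (per-lead filtering, squared-lead RMS combination,
    combinational lead product, PCA and ICA lead reduction), adaptive
    amplitude thresholding with coarse/fine peak localization, and
    multilead fusion by logical AND/OR, majority polling, or simple
    coupling. Includes WFDB and CSV readers/writers, beat-by-beat
    evaluation against reference annotations (sensitivity, specificity,
    positive predictive value, accuracy, error), K-fold threshold
    tuning, per-day error profiling, and a synthetic multilead ECG
    generator with controllable noise for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
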