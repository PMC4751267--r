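Package: snrlb
Title: Bootstrap Signal-to-Noise Confidence Intervals for ERP Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Objective subject exclusion for event-related potential (ERP)
    studies. Quantifies the quality of a subject's evoked response as the
    lower bound of a bootstrap confidence interval on the ERP
    signal-to-noise ratio (SNR-CI). Segments are resampled with
    replacement from the subject's full trial pool, signal averaged,
    baseline corrected, and scored as 20*log10(RMS_post/RMS_pre); the
    lower bound of the 90% percentile interval of the resulting SNR
    distribution (SNR_LB) is compared against a decibel criterion
    (recommended minimum 3.0 dB) to retain or exclude the subject.
    Includes a synthetic ERP subject simulator (canonical Gabor-plus-
    Gaussian waveform in low-passed 1/f noise), Monte Carlo validation
    studies (bootstrap-count error, presence and quality ROC analyses,
    zero-SNR noise calibration, fit-correlation), preprocessing
    utilities (baseline correction, linear detrending, amplitude-based
    artifact rejection, electrode pooling), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
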