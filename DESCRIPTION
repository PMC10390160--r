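Package: mousehrv
Title: Heart Rate Variability Analysis for Anesthetized-Mouse ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end heart rate variability (HRV) pipeline for short
    single-lead murine electrocardiograms: Pan-Tompkins QRS detection scaled
    to mouse timing, RR tachogram construction with ectopy flagging, Berger
    resampling to a uniform 10 Hz interval signal, time-domain indices
    (SDNN, RMSSD, TINN, mean HR), Welch spectral analysis over murine
    VLF/LF/HF bands, detrended fluctuation analysis, Poincare SD1/SD2, and
    approximate/sample entropy, together with the group-comparison
    statistical layer (Shapiro-Wilk screening, Welch and pooled t tests,
    one-way ANOVA, summary-statistic inference). Includes an integral
    pulse frequency modulation (IPFM) generator of synthetic RR series and
    raw ECG with presets emulating ketamine+xylazine, pentobarbital and
    pentobarbital+fentanyl anesthesia, so the whole pipeline is testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
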