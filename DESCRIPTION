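Package: physiopair
Title: Paired EEG and Heart Rate Variability Analysis for Two-Condition Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of paired-design EEG/ECG experiments.
    Generates synthetic multichannel EEG, coupled cortical ROI source
    series, and RR-interval series with controlled statistical structure,
    and analyses them end to end: zero-phase band-pass preprocessing with
    windowed artifact rejection, Welch relative band power and frontal
    alpha asymmetry, Lorenz-plot heart rate variability indices (SD1/SD2,
    CSI, CVI, first-vs-last-minute change scores), lagged phase
    synchronization connectivity, and a normality-routed paired statistics
    layer with rank-biserial and Cohen's d effect sizes,
    Benjamini-Hochberg and permutation max-statistic corrections, and an
    a-priori power calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
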