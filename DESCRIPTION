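Package: seldrift
Title: Classifying Selection and Drift in Frequency Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a time series of variant frequencies was
    produced by neutral stochastic drift or by directional selection. Provides a
    Wright-Fisher forward simulator with a selection-pressure sampling
    probability and a corpus-style distortion pipeline (Gaussian frequency
    noise, temporal binning, zero padding); the Frequency Increment Test with
    Shapiro-Wilk normality gating and absorption truncation; a one-dimensional
    residual-network time-series classifier trained on freshly simulated
    batches; and an evaluation harness that compares the two detectors
    (per-coefficient accuracy, selection-by-binning error grids, bootstrap
    false-positive curves, cross-binning consistency summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
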