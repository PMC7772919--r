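Package: ecgbw
Title: Wavelet-Based Baseline-Wander Removal Benchmarks for ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Removes low-frequency baseline wander from electrocardiogram
    (ECG) recordings by zeroing selected levels of a Maximal Overlap
    Discrete Wavelet Transform (MODWT) and benchmarks every combination of
    14 orthogonal wavelets (Daubechies, Symlets, Coiflets, Fejer-Korovkin,
    discrete Meyer) and preserved-level range on semi-synthetic data: real
    or synthetic ECG excerpts superimposed with known sinusoidal, step and
    spike trends, scored by mean square error against the known clean
    signal.  Includes a self-contained MODWT/inverse-MODWT engine with
    circular boundary handling, a seeded synthetic ECG generator, a WFDB
    (PhysioNet) excerpt reader, and tidy result tables with ggplot2
    heatmaps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    yaml
Config/testthat/edition: 3
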