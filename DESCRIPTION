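Package: ielm
Title: Imbalance-Aware Extreme Learning Machine Ensembles for EEG Stress
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of psychophysiological stress states from
    single-channel EEG under class imbalance. Implements rhythm-band
    decomposition (delta, theta, alpha, beta, gamma), four nonlinear
    band features (rescaled-range Hurst exponent, fluctuation index,
    sample entropy, permutation entropy), accuracy-weighted feature
    fusion, and a family of extreme learning machine (ELM) classifiers:
    plain ridge ELM, cost-weighted ELM, label-weighted ELM, classic
    AdaBoost, and an imbalance-aware boosted ensemble (IELM) that
    initialises and updates its sample-weight distribution per label and
    class block from per-label imbalance ratios. A seeded synthetic EEG
    generator (fractional Gaussian noise plus band-limited oscillations
    with class-dependent amplitudes) makes the full pipeline runnable
    and testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
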