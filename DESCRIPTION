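Package: nrmd
Title: Nostril-Excitation Resonance Measurement for Hypernasality Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal chain for detecting hypernasality from broadband noise
    excitation at the nostrils (nRMD). Synthesizes pseudorandom multi-harmonic
    excitation signals, estimates unit-less vocal/nasal tract transfer-function
    ratios by rectangular-window FFT averaging, removes superimposed voice-source
    harmonics by prominence-based peak pruning, computes nasalance from
    two-channel nasal/oral recordings, and provides the validation statistics
    used to compare normal and hypernasal speech conditions (rank correlation,
    Kolmogorov-Smirnov and Wilcoxon tests, rater agreement, Cohen's kappa,
    logistic calibration, and condition difference spectra). Includes a
    resonator-bank tract simulator that generates ground-truth captures for
    testing the full measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
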