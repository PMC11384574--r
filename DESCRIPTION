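Package: iscoh
Title: Infraslow Band-Power Envelope Coherence for Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and statistical calibration of magnitude-squared
    coherence (MSC) between infraslow (< 0.15 Hz) amplitude envelopes of
    band-limited electrophysiological signals. Provides per-second band-power
    envelope extraction in the canonical EEG bands, a Welch
    overlapped-segment-averaging (WOSA) coherence estimator with per-segment
    mean deletion, empirical null calibration on seeded 1/f (pink-noise)
    surrogate pairs with window-size and overlap sweeps, circular time-lag
    scanning with surrogate null models, rank-based condition comparison, and
    a study orchestrator with minimal EDF signal I/O. All analyses are fully
    reproducible from a single master seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
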