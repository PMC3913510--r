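Package: ssrtrace
Title: Stochastic Resonance Enhancement of Weak Chromatographic Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enhances weak peaks in uniformly sampled chromatograms with the
    single-well potential stochastic resonance algorithm (SSRA): the trace
    drives an overdamped particle in a quadratic potential, integrated with a
    fourth-order Runge-Kutta scheme, and the well steepness b is tuned by a
    vector-evaluated genetic algorithm (VEGA) against per-peak
    signal-to-noise and peak-symmetry objectives. Includes per-peak SNR and
    asymmetry metrics, a synthetic chromatogram generator with known ground
    truth, peak-area quantitation with ordinary least-squares calibration
    lines, and a command-line interface for simulation, enhancement,
    optimization and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
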