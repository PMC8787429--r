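Package: nervesignal
Title: Signal Analysis for Multichannel Small-Nerve Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of extracellular recordings from
    multichannel peripheral-nerve electrode arrays. Provides synthetic
    generators for stimulation-evoked sessions and chronic singing-related
    sessions with retrievable ground truth; preprocessing (common-mode
    subtraction, zero-phase Butterworth/Bessel bandpass filtering,
    squared-and-smoothed activity envelopes, noise metrics); evoked-response
    quantification with bootstrap null detection and four-parameter logistic
    recruitment-curve fitting; dynamic-time-warping alignment of song-motif
    renditions to a common template; chronic stability metrics (envelope
    correlation structure, running stability, per-motif peak-to-peak voltage
    and event rates); and closed-form electromechanical quantities for
    thin-film stretchable electrode arrays (bending strain, neutral-plane
    offsets, Poisson compression, current and charge density, compliance
    voltage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    minpack.lm,
    multcomp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
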