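Package: iowave
Title: Inferior-Olive Network Simulation and Spatio-Temporal Pattern Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of two-dimensional inferior-olive
    (IO) networks of Hodgkin-Huxley type neurons with subthreshold
    oscillations, coupled by diffusive gap junctions on a periodic lattice,
    with an optional event-driven cerebellar inhibitory feedback loop.
    Includes two bespoke analysis tools for the emerging spatio-temporal
    patterns: a per-frame spatial complexity metric C(t) based on the
    non-standard two-dimensional Haar wavelet transform, and a wave-front
    detector that fits circles through triples of suprathreshold cells,
    tracks arc centers and radii across frames, and classifies activity
    sources and sinks. Scenario configuration files drive reproducible
    simulation protocols (coupling regimes, cluster stimuli, reverberation,
    source-sink, inhibitory-loop modulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
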