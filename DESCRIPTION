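Package: memhh
Title: Hodgkin-Huxley and Memristive Hodgkin-Huxley Neuron Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of the space-clamped Hodgkin-Huxley
    (HH) squid-axon neuron and a memristive variant (MHH) in which the sodium
    and potassium channel conductances are supplied by flux-controlled
    memristors. Provides voltage- and temperature-dependent gating kinetics,
    declarative stimulus waveforms (constant, pulse, pulse train, sinusoid),
    current-clamp and ideal voltage-clamp integration with a fixed-step
    classical Runge-Kutta scheme, and trace analysis: spike detection
    (threshold-crossing and peak-prominence criteria), interspike intervals,
    per-series extrema, and paired HH-vs-MHH comparison reports. Traces are
    tibbles; results have tidy() and glance() methods and ggplot2 autoplot()
    support. Named experiment presets encode the standard comparison
    protocols once so analyses are reproducible from a single name.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
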