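Package: aeifnet
Title: Adaptive Exponential Integrate-and-Fire Networks with Autapses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates random networks of adaptive exponential
    integrate-and-fire (AEIF) neurons coupled by delayed conductance-based
    chemical synapses, including self-connections (autapses). Provides the
    network generator (excitatory/inhibitory populations, six connection
    classes, autapse assignment), a fourth-order Runge-Kutta integrator
    with delayed presynaptic conductance traces, and diagnostics for
    spike-train analysis: the Kuramoto order parameter from interpolated
    spike phases, interspike-interval coefficients of variation with
    spike/burst classification, subgroup firing rates, and time-averaged
    synaptic currents. Experiment drivers run conductance-plane sweeps and
    line scans and export raster tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
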