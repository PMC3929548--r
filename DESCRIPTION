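Package: ifgc
Title: Granger-Causality Reconstruction of Integrate-and-Fire Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conductance-based integrate-and-fire neuronal networks
    (standard, exponential, and mixed excitatory/inhibitory variants) under
    Poisson drive, and reconstructs their directed synaptic adjacency from
    recorded voltage or spike-train time series via time-domain conditional
    Granger causality. Vector autoregressions are estimated by Yule-Walker
    with BIC order selection; significance is assessed by an asymptotic
    chi-squared test or a ranked-value gap threshold. Spike-triggered
    correlation diagnostics on voltages and on regression residuals, together
    with residual cross-correlation approximations and the quadratic
    Granger-causality-versus-coupling-strength law, explain why the
    reconstruction succeeds.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
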