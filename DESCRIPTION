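Package: syncshot
Title: Subthreshold Voltage Statistics of Conductance-Based Neurons Driven
    by Synchronous Shot Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation and exact stationary moment analysis of
    all-or-none conductance-based (AONCB) neurons receiving correlated
    compound-Poisson synaptic input.  Input synchrony is modeled through the
    joint distribution of dimensionless conductance jumps, parametrized by
    beta-binomial and shared-input synchrony models.  The package provides an
    exact Marcus-rule jump simulator for feedforward populations, a
    finite-synaptic-time Euler integrator, closed-form stationary voltage
    moments (mean, variance, cross-neuron covariance, third moment and
    skewness) obtained from the PASTA ("Poisson arrivals see time averages")
    fixed point, small-weight approximations in terms of spiking correlation
    coefficients, and Monte-Carlo estimators with exact piecewise integration
    of event-anchored voltage trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
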