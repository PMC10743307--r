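Package: swarmchaos
Title: Scale-Free Chaos Analysis for the Harmonically Confined Vicsek Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the two-dimensional harmonically confined Vicsek model
    (self-propelled particles with metric alignment, angular noise, and a
    linear restoring force toward the origin) and provides the analysis stack
    needed to characterize its dynamical phases: largest-Lyapunov-exponent
    estimation by tangent-space propagation (Benettin), by the Gao-Zheng
    pair-separation slope, and by the scale-dependent Lyapunov exponent on
    embedded center-of-mass series; connected velocity-correlation functions
    in real and Fourier space with correlation length, susceptibility and
    correlation time; location of the critical confinement curves and
    estimation of static and dynamic critical exponents by finite-size and
    small-noise scaling; and multifractal dimension spectra, period detection
    and cluster counts for attractor classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
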