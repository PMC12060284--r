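Package: seepfate
Title: Fate of Methane from Seafloor Seeps in a Vertical Water Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale model chain for the fate of methane released as bubbles
    from seafloor seeps on a continental shelf. Includes a single-bubble
    dissolution model (Peng-Robinson gas density, modified Henry's law
    solubility, clean-bubble rise velocity and mass transfer correlations),
    Bayesian estimation of first-order biodegradation kinetics from
    tritium-tracer incubation experiments (maximum likelihood and
    affine-invariant ensemble MCMC), a Crank-Nicolson finite-volume solver for
    vertical diffusion-reaction transport of dissolved methane with
    wind-parametrized air-sea mass transfer, and annual ensemble analysis of
    the fate branching between direct bubble transport, ventilation to the
    atmosphere, and biodegradation. A synthetic-environment module generates
    seasonal eddy-diffusivity, hydrography and wind fields as well as simulated
    tracer datasets so that the full chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
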