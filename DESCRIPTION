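Package: needscape
Title: Neural Landscape Diffusion Models of Competing Homeostatic Needs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, closed-form theory, likelihood-based fitting and
    behavioural statistics for a stochastic dynamical model of how animals
    resolve competing homeostatic needs (thirst versus hunger). Position in a
    two-dimensional neural activity subspace diffuses by overdamped Langevin
    dynamics over an energy landscape whose Gaussian wells are deepened by the
    current need magnitudes; choices are emitted by a maximum-likelihood zone
    partition when reward cues arrive, and collected rewards feed back onto
    needs after a delay. The package provides the landscape and its analytic
    gradient, a compiled Euler-Maruyama session simulator (including
    optogenetic-style need perturbations and a forced-transition alternative
    model), Kramers transition rates and the time-dependent two-state
    transition matrix, Boltzmann equilibrium choice probabilities by
    quadrature, a joint negative log-likelihood fit of the gradient, noise and
    foraging-weight scales, synthetic Go/No-Go session generators, and the
    bout-persistence, need-regression and phase-portrait analyses used to
    compare model output with behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    e1071,
    pROC,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
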