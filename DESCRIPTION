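Package: biofilmosc
Title: Potassium Signaling and Oscillatory Growth in Bacillus subtilis Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator of electrochemical signaling and oscillatory
    growth in Bacillus subtilis biofilms. Implements a one-dimensional
    moving-domain reaction-advection-diffusion model in which metabolically
    stressed cells release potassium through Hodgkin-Huxley-style gates,
    hyperpolarize, and propagate a depolarizing wave that throttles growth at
    the nutrient-rich periphery; a two-dimensional flow-cell extension with a
    Stokes-flow approximation, steady fluid transport, growth-potential
    biomass expansion and level-set interface tracking; and the analysis
    procedures built on top of the model: oscillation-onset detection,
    onset-size experiments, period-versus-size curves, ablation variants, and
    finite-difference parameter sensitivity of the potassium oscillation
    magnitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
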