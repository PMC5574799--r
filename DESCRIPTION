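Package: rrbm
Title: Refined Resource Budget Model of Mast Seeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and stability toolkit for a refined resource budget
    model of mast seeding in perennial plants that reproduce both sexually
    and asexually. The annual reserve dynamics follow a piecewise-linear
    map with a lower threshold triggering asexual reproduction and an upper
    threshold triggering simultaneous sexual and asexual reproduction.
    Provides exact trajectory simulation with full cost accounting,
    closed-form fixed points with existence conditions and analytic
    Lyapunov exponents, a four-regime classification of the reproductive
    dynamics, long-run reproductive period detection, and phase-diagram
    parameter sweeps over the sexual/asexual allocation coefficients, plus
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
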