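Package: binswitch
Title: The Binary Switch Model of Density-Dependent Population Growth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Binary Switch Model, a five-parameter continuum
    growth law for crowded populations in which per-capita proliferation and
    death rates change abruptly when the number of occupied nearest-neighbour
    sites crosses a threshold density. Provides the full equilibrium and
    bifurcation analysis of the model (Weak, Strong, Reverse and Hyper-Allee
    effects, Extinction, Tangential Manifold, Triple Point and Junction
    Point), a stochastic exclusion-process simulator on a periodic hexagonal
    lattice whose ensemble mean recovers the continuum law, combined
    least-squares calibration of the model to multiple growth curves with
    discrete model selection over the threshold, and a synthetic growth-curve
    generator emulating U87 glioblastoma monolayer experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
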