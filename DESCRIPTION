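Package: irbrachy
Title: Monte Carlo Dosimetry for an Ir-192 HDR Brachytherapy Source in
    Heterogeneous Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photon-transport Monte Carlo simulation of a high-dose-rate
    Ir-192 brachytherapy line source in water, cortical-bone and
    inflated-lung phantoms and their planar interfaces.  Provides the
    five-line Ir-192 emission model, delta-tracking transport with
    Klein-Nishina Compton sampling and collision-kerma scoring on
    cylindrical and planar grids, extraction of TG-43 dose parameters
    (line-source geometry factor, radial dose function g(r), anisotropy
    function F(r,theta)), interface dose-difference profiles and isodose
    contours, and a synthetic point-dosimeter measurement generator for
    simulation-versus-measurement comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
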