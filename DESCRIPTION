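Package: diatherm
Title: Interface Heating in Layered Tissue Phantoms Under Therapeutic
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the heating of layered soft-tissue/bone phantoms under
    1 MHz physiotherapeutic ultrasound and analyses thermocouple endpoint
    temperatures at the layer interfaces.  Provides a registry of phantom
    material constants, a normal-incidence multiple-reflection model of the
    acoustic intensity field with transducer-bone reverberation, an explicit
    finite-volume solver for the perfusion-free Pennes bioheat equation on an
    axisymmetric grid, a fluid-solid mode-conversion reflectance calculation
    of the energy trapped between the transducer face and a bone layer, a
    seeded generator of synthetic thermocouple measurements, and the
    two-sample inference used to compare with-bone and without-bone arms
    (pooled t, Mann-Whitney U, Lilliefors normality screening, prospective
    sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
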