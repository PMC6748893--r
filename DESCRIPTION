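Package: clotsim
Title: Coupled Flow-Coagulation-Platelet Simulation of Clot Growth Under
    Arterial Shear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood clot growth on a thrombogenic (collagen + tissue
    factor) surface in a 2-D microfluidic channel under arterial wall shear
    (1000 1/s). Couples steady Stokes-Brinkman flow through the growing porous
    clot with reaction-convection-diffusion transport of a tissue-factor-pathway
    coagulation network (nine proteins and their complexes), four platelet
    phenotype fields with margination, adhesion, aggregation and
    thrombin-driven activation, and a Kozeny-Carman platelet/fibrin resistance
    closure. Includes core/shell clot-structure extraction, flow through
    measured clot shapes, fluorescence deposition-profile processing
    (alignment, spurious-profile filtering, ensemble statistics), the
    Jarque-Bera/t/rank-sum/Bonferroni group-comparison pipeline, and a
    synthetic microfluidic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
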