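Package: monoct
Title: Virtual Monoenergetic Micro-CBCT Simulation and Beam-Hardening
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired polyenergetic (60 kVp) and monoenergetic
    (35 keV) cone-beam X-ray projections of procedural mouse-like and
    cylinder phantoms in the stationary source/detector "pancake" geometry
    of preclinical irradiation cabinets, trains a projection-domain U-Net
    to synthesize virtual monoenergetic projections from polyenergetic
    ones, reconstructs volumes with the Feldkamp-Davis-Kress algorithm,
    and quantifies beam-hardening removal (cupping, image uniformity,
    percentage error). Ships embedded elemental mass-attenuation tables,
    a filtered-bremsstrahlung tube spectrum model, an exact Siddon ray
    tracer, and a compiled convolutional network with Adam training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
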