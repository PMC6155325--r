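Package: spraydep
Title: Quantitative Analysis of Microfluidic Spray Deposition for AFM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying microfluidic spray deposition of
    biomolecules for atomic force microscopy (AFM). Implements particle
    (local-maxima) detection in AFM height maps, the nearest-neighbour
    angle-distribution order parameter with its binomial null model,
    uncertainty, inverse-variance combination across images and null
    hypothesis p-value; sessile and in-flight droplet evaporation physics
    (spherical-cap geometry, Bond number, Maxwell evaporation, pinned
    contact-line drying, coalescence/coverage regime); surface-occupancy
    statistics (nearest-neighbour distances versus sprayed concentration,
    per-particle cross-sectional heights); and a synthetic AFM height-map
    generator with ground truth for validating the full analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
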