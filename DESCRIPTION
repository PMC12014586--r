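Package: spheroidECM
Title: Hybrid Agent-Based Simulation of Cancer Spheroid Growth in a
    Stiffened Collagen Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A centre-based, off-lattice agent model of tumour spheroid growth
    and invasion coupled to a continuum extracellular-matrix (ECM) density
    field. Cells interact mechanically with each other (adhesion/repulsion)
    and with the ECM (density-dependent adhesion speed and repulsion),
    degrade the matrix locally, and proliferate under crowding and matrix
    inhibition. Ribose-induced collagen cross-linking is modelled as an
    exponential attenuation of the ECM degradation rate and of the maximum
    cell-ECM interaction speed. Includes scenario presets for non-invasive
    and invasive breast-cancer cell lines and an MMP-inhibition condition,
    plus the measurement stack used to quantify spheroid growth: rasterized
    union-of-disks area, cell counts, and Delaunay mean distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
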