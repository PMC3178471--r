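Package: bifex
Title: Bifurcation Exponent Estimation and Murray's Law Analysis for
    Vascular Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests the principle of minimum work (Murray's law) at arterial
    bifurcations such as the carotid. Generates voxelized bifurcation
    phantoms with known ground truth, extracts vessel centerlines from
    binary masks by distance-transform-weighted minimal cost paths,
    measures branch radii by maximally inscribed spheres and by
    cross-sectional area, solves the bifurcation power law
    r_parent^n = r_daughter1^n + r_daughter2^n per bifurcation by
    root finding, and estimates cohort exponents by Gauss-Newton
    nonlinear regression. Includes Murray's energy-minimization model
    (Poiseuille pumping power plus metabolic cost of blood volume) and
    an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
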