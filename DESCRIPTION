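Package: sffscan
Title: Scattering-Foil-Free Electron Beam Scanning Dose Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study scanned small-field electron beams on curved
    surfaces. Reads or synthesises electron percent-depth-dose curves and
    off-axis profiles, computes beam-characteristic metrics (R50, practical
    range, bremsstrahlung contamination, output ratio, 2%/1 mm curve
    agreement), reconstructs separable 3D single-beam dose kernels, places
    surface-normal beams on cylindrical and spherical voxel phantoms at
    configurable angular and longitudinal scanning resolutions, superposes
    kernels into the phantom frame, and evaluates the resulting plans with
    dose-volume histograms, conformity and homogeneity indices and body
    mean dose, including full scanning-resolution sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
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
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
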