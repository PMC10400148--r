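Package: kranzsim
Title: 3D Reaction-Diffusion Simulation of C4 Photosynthesis in a Kranz Leaf
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-based simulator of C4 (maize-type, NADP-ME) leaf
    photosynthesis. Generates synthetic three-dimensional Kranz anatomy
    (epidermis, stomata, intercellular airspace, mesophyll and bundle
    sheath cells with vacuoles and chloroplasts, vascular bundle),
    propagates light through the labelled tissue with a Monte Carlo
    photon-transport model (Henyey-Greenstein scattering, Fresnel
    interfaces), converts absorbed photons into linear/cyclic electron
    transport and ATP/NADPH production per cell class, and solves the
    steady-state coupled reaction-diffusion system for CO2, bicarbonate,
    and O2 with membrane, cell-wall, and plasmodesmatal resistances.
    Reports whole-leaf gas exchange (net photosynthesis, leakiness,
    bundle-sheath CO2) and supports aggregative and avoidance
    chloroplast-movement scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
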