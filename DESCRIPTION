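Package: lcnflow
Title: Load-Induced Interstitial Fluid Flow in Osteocyte Lacunocanalicular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the osteocyte lacunocanalicular network (LCN) of human
    osteons as a hydraulic circuit on a weighted spatial graph and solves for
    load-induced interstitial fluid flow. Node pressures are obtained from
    Kirchhoff's current law via a sparse reduced graph Laplacian with the
    Haversian canal as grounded reference, under two boundary conditions: a
    fixed trans-osteonal pressure difference (intrinsic permeability) and
    homogeneous-strain pore-volume sources (deformation-induced flow). Includes
    canalicular Darcy conductivities, fluid velocities and cell-process shear
    stresses, structural network metrics, pressure profiles and angular
    heterogeneity, cumulative shear-exceedance distributions, seeded generators
    for synthetic ordinary and osteon-in-osteon networks, and a reproducible
    generate-solve-analyze pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
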