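Package: foveamap
Title: Analytic Retino-Cortical Projection Models for the V1-V2-V3 Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytic models of the projection from the visual field onto
    the flattened surface of primate early visual cortex.  Implements the
    complex-logarithm map family for area V1 (monopole and dipole variants),
    their angle-compressed "double-sech" versions with polar-invariant areal
    magnification, the mirrored wedge construction of the full V1-V2-V3
    complex, and a banded variant in which the foveal representations of V2
    and V3 form bands around the tip of V1 rather than converging to a
    point.  Provides numerical estimators of local anisotropy, meridional
    anisotropy and areal cortical magnification on projected grids,
    iso-eccentricity and meridian contour extraction, numeric map
    inversion, least-squares fitting of model parameters to sparse
    retinotopic samples or magnification curves, a synthetic-retinotopy
    generator for parameter-recovery studies, and a command-line interface
    with CSV/JSON/SVG writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
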