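Package: femurflow
Title: Ricci-Flow Conformal Parametrisation and Statistical Mapping of
    Proximal Femur Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dense correspondence analysis of open triangulated
    bone surfaces. A discrete surface Ricci flow computes flat metrics for
    genus-0 surfaces with one boundary under free-boundary (disk) and
    zero-curvature (annulus) conditions; conformal-factor peaks locate the
    femoral head, greater trochanter and lesser trochanter; meshes are slit,
    normalised to a common strip frame and mapped to an annulus. A canonical
    2D template corrected by compactly supported Wendland radial basis
    functions is resampled on each subject to build isotopological surface
    sets. Downstream morphometry includes cortical thickness, generalised
    Procrustes alignment, shape modes and scale factors, and node-wise
    statistical parametric mapping with supra-threshold clustering and
    permutation or random-field-theory cluster-level correction. A seeded
    synthetic femur generator provides meshes and cohorts with known ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    minpack.lm,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
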