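Package: csr3d
Title: Testing Complete Spatial Randomness on Bounded Convex 3D Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional summary statistics and Monte Carlo tests of complete
    spatial randomness (CSR) for point patterns observed on bounded convex
    surfaces in three dimensions, such as molecules imaged on cell membranes.
    Patterns on a convex shape are mapped to the unit sphere, where a Poisson
    process remains Poisson with a transformed intensity; inhomogeneous K-, F-,
    H-, J- and P-function estimators are computed on the sphere together with
    their theoretical means, variances and covariances. Two Monte-Carlo
    calibrated test statistics (a variance-stabilised analogue-L deviation and
    a standardised K deviation) test the CSR hypothesis on the original shape.
    Includes simulators for CSR, Matern I/II hard-core and Thomas cluster
    processes on spheres, ellipsoids and cubes, intensity calibration for
    Matern II thinning, and a scaled reproduction of the calibration and power
    study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    pracma
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
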