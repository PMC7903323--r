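## shared shape objects: geodesic meshes and K~ geometry are cached inside
## the shape objects, so reusing them across test files keeps the suite fast
SPH <- cs_sphere()
ELL13 <- cs_ellipsoid(1, 1, 3)
CUBE1 <- cs_cube(1)
ELL08 <- cs_ellipsoid(0.8, 0.8, solve_c_for_area(0.8))
ELL04 <- cs_ellipsoid(0.4, 0.4, solve_c_for_area(0.4))
## near-spherical ellipsoid: exercises the mesh geodesic machinery against
## the analytic great-circle oracle
ESPH <- cs_ellipsoid(1, 1, 1 + 1e-7)

## documented accuracy of the mesh geodesic approximation (see the methods
## vignette): absolute error about a quarter mesh edge, relative ~2% in the
## short-range transition band
GEO_TOL_ABS <- 0.015
GEO_TOL_REL <- 0.02
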