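Package: lvotflow
Title: Moving-Boundary Hemodynamics of the Left Ventricular Outflow Tract
Version: 0.1.0
Authors@R:
    person("lvotflow", "developers", email = "lvotflow@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computational assessment of how aortoseptal-angle
    steepening and a discrete subaortic stenosis (DSS) lesion alter left
    ventricular outflow tract (LVOT) hemodynamics.  Builds parametric 2D
    left-ventricle geometries (normal angle, steep angle, steep angle with a
    compliant lesion), generates synthetic cyclic wall motion, derives
    phase-switched inlet/outlet velocity boundary conditions from the chamber
    area rate, solves the incompressible Reynolds-averaged Navier-Stokes
    equations on a moving unstructured mesh (arbitrary Lagrangian-Eulerian
    finite volumes with an optional SST k-omega closure), couples a linear
    elastic lesion through partitioned fluid-structure interaction, and
    computes wall shear stress metrics (temporal shear magnitude and
    gradient, oscillatory shear index), vorticity, turbulence kinetic energy
    and Reynolds shear stress endpoints together with cross-model comparison
    ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
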