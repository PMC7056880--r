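# lvotflow

Desk-scale computational assessment of how aortoseptal-angle (AoSA)
steepening and a discrete subaortic stenosis (DSS) lesion alter left
ventricular outflow tract (LVOT) hemodynamics.

DSS is an obstruction of the LVOT caused by a fibromuscular membrane that
forms on the septal wall upstream of the aortic valve, and it is strongly
associated with steep aortoseptal angles.  A candidate mechano-etiology holds
that angle steepening overloads the septal wall shear environment, promoting
fibrosis where lesions form, and that the lesion in turn creates stenotic,
turbulent outflow.  `lvotflow` probes this pathway with three 2D
moving-boundary flow models:

* **N-LV** — normal AoSA (130 deg),
* **S-LV** — steep AoSA (110 deg), same chamber otherwise,
* **DSS-LV** — S-LV plus a compliant lesion tab (10 mm x 1 mm,
  E = 0.37 MPa, nu = 0.49) on the septal wall, reducing the 18.6 mm
  luminal width by 25%.

## What the package computes

The chamber wall moves through a synthetic cardiac cycle (period
T = 0.772 s; diastolic filling with E- and A-waves for 0 < t < 0.480 s,
systolic ejection after; 29 contour frames of 80 nodes each, interpolated in
time with periodic cubic splines).  Valve action is a velocity switch: during
diastole the aortic outlet is a zero-velocity wall and the mitral inlet
carries a plug velocity equal to the chamber area rate over the inlet width
(dA/dt / w); during systole the roles swap.

The flow solves the Reynolds-averaged incompressible Navier-Stokes equations
in arbitrary Lagrangian-Eulerian (ALE) form on a moving unstructured
triangle mesh (cell-centred finite volumes, exact face swept volumes for
discrete geometric conservation, slope-limited second-order upwind
convection with Adams-Bashforth 2, non-incremental pressure projection
driving the continuity residual below 1e-3, optional SST k-omega closure
with low-Reynolds wall treatment).  The mesh follows the wall by
inverse-distance interior deformation with automatic remeshing and field
transfer when cells distort.

Wall shear endpoints follow the standard definitions on the
ensemble-averaged Cartesian shear component
`tau12 = mu (du1/dx2 + du2/dx1)` evaluated at three 2-mm septal sites
bracketing the septal crest:

* `TSM = (1/T) \int |tau12| dt` (temporal shear magnitude, Pa)
* `TSG = (1/T) \int |d tau12/dt| dt` (temporal shear gradient, Pa/s)
* `OSI = 1/2 [1 - |\int tau12 dt| / \int |tau12| dt]` (0 unidirectional,
  0.5 purely oscillatory)

plus field-level vorticity `(du2/dx1 - du1/dx2)`, modeled turbulence kinetic
energy, Boussinesq Reynolds shear stress, peak LVOT velocity, effective jet
diameter (contiguous span above 10% of the sectional maximum) and
cross-model fold changes.  The DSS lesion's motion is modeled by a
plane-strain Q4 finite-element tab reduced to its leading in-fluid
vibration modes (hydrodynamic added mass included); the desk-scale default
drives those modes one-way from the computed wall traction, with a two-way
partitioned (interface quasi-Newton) mode available.

## Worked example

```r
library(lvotflow)

geom <- build_geometry("DSS-LV")
print(geom)
#> lvot_geometry: DSS-LV
#>   AoSA (requested/measured): 110 / 110 deg
#>   boundary vertices: 382  area: 2928.8 mm^2
#>   lesion: L = 10 mm, t = 1 mm, protrusion = 4.65 mm

min_lumen_width(geom)
#> [1] 13.95128        # 18.6 mm x 0.75: the 25% stenosis

# one-period oscillatory-shear record: the OSI limiting cases
T <- 0.772; tg <- (0:999) / 1000 * T
compute_osi(list(times = tg, tau = sin(2 * pi * tg / T), period = T))
#> [1] 0.5            # purely oscillatory, bidirectional shear
compute_osi(list(times = tg, tau = rep(1, 1000), period = T))
#> [1] 0              # purely unidirectional shear

# a full desk-scale run (about 1-2 minutes for N-LV)
run  <- run_cycle(run_config(model_id = "N-LV", cell_size = 1.5e-3,
                             n_cycles = 2))
summ <- endpoint_summary(run)
print(summ)
#> endpoint_summary: N-LV
#>   site 1: TSM 0.2078 Pa, TSG 5.108 Pa/s, OSI 0.070
#>   site 2: TSM 0.732 Pa, TSG 13.35 Pa/s, OSI 0.025
#>   site 3: TSM 1.05 Pa, TSG 17.6 Pa/s, OSI 0.006
#>   peak LVOT velocity 1.231 m/s; jet diameter 18.60 mm
#>   LVOT <|vorticity|> 44.9 1/s; max TKE 0 m2/s2; peak RSS 0 Pa
```

The TSM here *decreases* from site 3 to site 1 on the idealized desk-scale
geometry (a documented deviation from the directional expectation; see the
vignette's limitations section), while the steep-angle overload at site 1
(S-LV vs N-LV) and the stenotic DSS jet (higher peak velocity, smaller
effective diameter) are reproduced.

`run_cycle()` reports the per-step continuity residual (must stay below
1e-3), the open-boundary flux against the chamber area rate (mass closure)
and a cycle-to-cycle periodicity metric; `compare_models()` forms the
velocity/vorticity fold changes and site-wise TSM/TSG differences between
two models.  The command line mirrors the pipeline:

```sh
Rscript inst/cli/lvotflow.R run-all --model DSS-LV --out-dir out --cycles 2
Rscript inst/cli/lvotflow.R mesh-sensitivity --model N-LV \
    --sizes 0.0018,0.0014 --out sens.csv
```

## Scope

2D only; idealized smooth chamber outline shared by all three models (the
study-specific patient anatomy is not deposited); no valve leaflets or
papillary muscles; Newtonian blood (rho = 1050 kg/m^3,
mu = 3.5e-3 kg/m/s).  See `vignettes/lvot-hemodynamics.Rmd` for the model
assumptions, numerical choices and known limitations.
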