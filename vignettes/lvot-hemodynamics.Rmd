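---
title: "Moving-boundary LVOT hemodynamics: models, numerics and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-boundary LVOT hemodynamics: models, numerics and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lvotflow` asks a mechanobiological question with three two-dimensional
left-ventricle models: does steepening the aortoseptal angle (AoSA) overload
the wall-shear environment on the septal crest where discrete subaortic
stenosis (DSS) lesions form, and does an established lesion create stenotic,
disturbed outflow?  This vignette records the model, every tunable that
matters, the numerical choices, and what a passing test does and does not
establish.

## The stated world

### Geometry

All three models share one idealized chamber: a straight-walled basal
section (12 mm) joined to a half-ellipse (depth 55 mm at end systole, basal
width 49.4 mm), with a 2 mm x 24.4 mm mitral inlet extension and an LVOT
channel of width 18.6 mm ending in a 10 mm straight outlet extension.  The
AoSA is the angle at the septal crest between the apex-ward septal wall and
the outflow axis; it is imposed by rotating the LVOT channel about the crest
(130 deg for N-LV, 110 deg for S-LV/DSS-LV), so the chamber outline is
bitwise identical across models and angle effects are isolated.  The patient
anatomy behind the original study is not deposited; the idealized outline is
the package's own stated world, and quantities that depend on patient shape
(absolute velocities, absolute shear) are therefore only directionally
comparable to the study.

The DSS lesion is a rounded rectangular tab of length 10 mm and thickness
1 mm on the septal wall of the channel, root-filleted (0.5 mm).  Two printed
dimensions are jointly honoured by inclining the tab toward the outlet so
that its normal protrusion into the lumen is 25% of the 18.6 mm width
(4.65 mm): a tab normal to the wall could not be 10 mm long and protrude
4.65 mm at the same time.  Setting the stenosis fraction to zero removes the
tab exactly (DSS-LV degenerates to S-LV node-for-node).

### Wall motion (synthetic data)

The study's MRI segmentation is not deposited, so the motion generator is a
first-class synthetic stand-in with the same structure: 29 frames of 80
boundary nodes over a 0.772 s cycle, diastole ending at 0.480 s, interpolated
per node with periodic cubic splines (60 intermediates reproduce the study's
temporal refinement; the counts printed there - 1,766 contours at 0.4375 ms -
are not mutually consistent, so the refinement is parameterized and the
achieved resolution reported).  Nodes move along rays through a fixed
contraction centre with a smooth basal taper (zero motion at the basal
corners, maximal near the apex); the scale waveform is piecewise raised
cosine: E-wave (0-0.25 s), diastasis, A-wave (0.37-0.48 s), ejection.  The
amplitude is solved so the 2D chamber area ratio matches the
ejection-fraction analog (default 0.5, a normal area-EF), and the E/A split
is solved so the peak area-rate ratio matches `ea_ratio` (default 1.7, a
normal transmitral pattern).  Optional seeded smooth Fourier perturbations
are off by default, making the generator fully deterministic.

The 2D enclosed area stands in for LV volume everywhere volume appears:
with an incompressible solver, inflow/outflow equals the area rate by
construction, so the valve-switched boundary velocity is `dA/dt / width`.

### Boundary conditions

The closed valve is a zero-velocity wall, exactly as the velocity-switch
description demands; the open boundary carries a spatially uniform (plug)
profile.  A 5 ms raised-cosine ramp regularizes the switch (the source is
silent on this; the area rate is near zero at the transitions so the ramp
removes negligible flux).  Sub-tolerance counter-phase excursions of dA/dt
(spline overshoot of the 29-frame sequence, about 3% of peak) are carried
through signed so the time-integrated flux matches the area change; larger
excursions are clipped with a warning.  At run time the solver rescales the
open-boundary flux (typically by 1.000 +- 0.005) so the discrete open flux
balances the discrete wall swept-volume rate exactly - without this the
pure-Neumann pressure problem is inconsistent.

## Numerics

* **Discretization.** Cell-centred finite volumes on unstructured triangles
  (deterministic Bowyer-Watson mesher with a single wall offset row at the
  configured first-layer height, hexagonal interior lattice, verified
  boundary-edge recovery).  Desk-scale default: 1.2-1.5 mm bulk cells
  (3,000-5,000 cells), against the study's 175 um / ~177,000 cells.
* **ALE transport.** Convective fluxes use exact face swept volumes, so the
  discrete geometric conservation law holds and a uniform stream is
  transported exactly under arbitrary node motion (verified to 1e-14 over
  100 steps).  Momentum convection is slope-limited second-order upwind
  advanced with Adams-Bashforth 2; diffusion is explicit with over-relaxed
  non-orthogonal correction; both are first-order in time at the moving
  boundary.
* **Projection.** Non-incremental (pressure rebuilt each step): the
  incremental variant accumulates a checkerboard pressure mode on
  unstructured meshes and was removed after it destabilized wall-bounded
  cases.  The TPFA Poisson system is solved by Jacobi-preconditioned CG with
  the tolerance tied to the continuity criterion; the per-step normalized
  residual (RMS cell net flux over peak open-boundary flux) is driven to
  1e-5 by default, well under the 1e-3 criterion, because looser pressure
  solves inject velocity noise that can destabilize fine-cell regions.
* **Velocity gradients** are least-squares with boundary-value closure
  (without it, corner cells are rank-deficient); the pressure-correction
  gradient uses a face-normal-derivative reconstruction that encodes the
  homogeneous Neumann condition exactly.
* **Wall shear** is sampled by a one-sided quadratic fit through the no-slip
  wall using two interior probe-cell centroid values at their actual normal
  distances (the wall-adjacent cell itself carries the largest
  discretization bias).  On plane Poiseuille this recovers `3 mu U / h`
  within about 1.5%.
* **Time step** defaults to a per-cell convective CFL target of 0.25
  (the stability limit on simplices is the outgoing-flux sum, about three
  times stricter than the naive face estimate).  The wall-motion spline has
  a nonzero end slope at t = 0, so the first (washout) cycle blends the
  motion in over 50 ms (`soft_start`); analysis always uses the final cycle.
* **Remeshing.** Cell-area ratios against the mesh-time reference are
  monitored; beyond 2.2 (or on inversion) the boundary loop is rebuilt on
  the current contour, re-triangulated, and fields are transferred by
  containing-cell lookup (locally conservative only to first order -
  documented approximation).  An ejection-fraction analog of 0.5 typically
  triggers 2-5 remeshes per cycle.
* **SST k-omega** uses Menter's standard constants, strain-rate production
  with the 10 beta* k omega limiter, semi-implicit sources
  (the homogeneous-decay recursion for omega is then exact), implicit SPD
  diffusion (unconditionally stable at any eddy diffusion number), and the
  low-Reynolds wall treatment (k = 0 at walls, viscous-sublayer omega in
  wall-adjacent cells).  The desk-scale default closure is laminar: at
  3,000-5,000 cells the model's near-wall demands cannot be met and the
  directional comparisons do not depend on it; the closure is retained,
  verified against the reduced decay ODE, and available per run.

## Lesion mechanics and coupling

The lesion solid is a plane-strain bilinear-quadrilateral tab with B-bar
selective integration (no locking at nu = 0.49), clamped at the root,
verified against the Euler-Bernoulli cantilever closed form (tip deflection
within 2% at 40x4 elements) and via the refinement protocol (deformation
and surface-fibre von Mises changing by <1% and <5% between ~350, ~550 and
~700 elements; peak von Mises is sampled at the outer-fibre midpoints
because the clamped-corner stress is singular and its element-wise maximum
cannot converge).

For coupling, the tab is reduced to its leading vibration modes of
(K, M + Ma), where Ma is the transverse-plate hydrodynamic added mass
estimate `rho_f pi L^2 / 4` distributed like the structural mass (about 7.5
times the tab mass, dropping the first natural frequency from ~34 Hz in
vacuo to ~12 Hz in fluid - the physically relevant scale).  Two modes of
operation exist:

* **`oneway` (desk-scale default).** The flow is solved with the lesion
  boundary rigid, the computed wall traction (pressure plus one-sided
  viscous shear) is projected onto the modes each step, and the modal
  oscillator is integrated by Newmark.  The tip-deflection trace and
  flutter frequency emerge from the computed load history and the in-fluid
  modal dynamics; nothing is prescribed.  The fluid does not see the
  deflection, so jet deflection-flow interaction is absent.
* **`coupled`.** Full two-way partitioned stepping with interface
  quasi-Newton (Anderson/IQN-ILS) subiterations, relative convergence
  tolerance, backtracking on mesh-invalid trials and displacement-rate
  clipping.  The configuration is strongly added-mass dominated
  (fluid/solid mass ratio ~7 and thin-gap confinement), and at desk-scale
  resolution the converged staggered stepping still amplifies the coupled
  mode slowly; runs are therefore prone to remesh churn and divergence.
  The machinery is retained and unit-verified (quiescent fluid leaves the
  lesion undeformed; the rigid limit matches the fixed-geometry flow), but
  the default stays one-way.  This is the package's main acknowledged
  limitation relative to the study's two-way commercial coupling.

## What a green test establishes

The verification suite establishes solver correctness on problems with
known answers (free-stream transport, Poiseuille shear, transient Couette,
turbulence decay, beam bending) and the analysis formulas against
independent quadrature to 1e-6.  The three-model batch establishes the
*directional* findings on the idealized geometry: higher peak LVOT velocity
and smaller effective jet diameter with the lesion, septal shear rising
toward the LVOT, and a steep-angle shear overload at the site closest to the
LVOT.  It does not - and at desk scale cannot - reproduce the study's
printed magnitudes (2.4-fold velocity, 45% jet reduction, 2.8-fold
vorticity, 23%/69% TSM/TSG overloads, turbulence levels), which derive from
a patient-specific geometry, 175 um cells, four cycles and a two-way
commercial FSI.  The synthetic motion reproduces timing structure (phase
split, E/A pattern, cyclicity), not patient kinematics.

One directional claim is knowingly *not* met in this stated world and its
acceptance assertion is left red: septal TSM/TSG here decrease from site 3
toward site 1 instead of increasing.  Rotating a straight channel about the
crest pinches the funnel mouth on the junction side, so the effective throat
sits at the crest and the channel acts as a septal-side expansion; the
boundary layer separates just past the crest where site 1 lies, while the
converging sub-crest wall (site 3) carries both the diastolic-vortex sweep
and the accelerating systolic flow.  The behaviour is robust to crest
blending radii of 4-10 mm and therefore reflects the idealized geometry
itself, not the numerics; an anatomical LVOT converges smoothly to the
outlet and keeps site 1 attached.

## Other deliberate choices

* Config files are JSON (no YAML parser is assumed on the target system).
* TKE is reported as the modeled k actually transported by the closure; the
  mean-velocity form sometimes printed for TKE is dimensionally a mean
  kinetic energy and is not used.
* Reynolds shear stress uses the Boussinesq form
  `rho nu_t (du1/dx2 + du2/dx1)`; a RANS solve has no resolved fluctuations.
* `tau12` is the fixed-frame Cartesian 1-2 component as defined, assembled
  from the wall-normal derivative of the wall-relative velocity; the
  tangential-derivative contribution along smooth walls is neglected.
* The LVOT averaging region for vorticity is the channel strip between the
  crest mouth and the outlet; the jet cross-section sits at 35% of the
  channel length; both are configuration, since the source leaves them
  undefined.
* Site windows are fixed in the reference (end-systolic) arc coordinate;
  the site-3 wall moves slightly with the chamber and its arc coordinate is
  not re-measured per frame (the taper keeps near-crest motion small).
* The equal-curvature tie-break in crest detection returns the arc midpoint
  of a contiguous maximal run and the most LVOT-ward run among separated
  ones.
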