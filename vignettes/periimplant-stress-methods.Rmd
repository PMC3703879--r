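---
title: "Methods: finite-element evaluation of platform-switched implants"
author: "osseoFEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element evaluation of platform-switched implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

osseoFEM compares threaded, platform-switched dental implants by the stresses
they induce in the surrounding bone under a static functional load.  The
pipeline is: parametric implant/abutment/bone geometry, graded quadratic
tetrahedral meshing, linear isotropic 3D elasticity, Zienkiewicz–Zhu error
recovery, and principal-stress postprocessing over peri-implant control
volumes.  Units are mm–N–MPa; the implant axis is $z$ (intrusive direction),
$x$ is buccolingual, $y$ mesiodistal.

The biomechanical question is load transfer: osseointegrated implants bond
directly to bone, so occlusal forces pass from the prosthetic crown through
the implant wall into the cortical shell and trabecular core.  Overload
concentrates at the crestal cortical bone around the implant neck and at the
trabecular interface near the apex, and sustained overload drives marginal
bone resorption.  Platform switching — an abutment narrower than the implant
collar — moves the implant–abutment junction inward and permits horizontal
bone apposition over the platform, which redistributes crestal stress.

## The model

All materials are homogeneous, isotropic and linearly elastic:
titanium alloy (Ti6Al4V) $E = 114\,$GPa, $\nu = 0.34$ for implant and
abutment; type-II quality bone with cortical $E = 13.7\,$GPa, trabecular
$E = 0.5\,$GPa, $\nu = 0.30$ for both.  Complete osseointegration is assumed:
the bone–implant interface is a shared-node surface (displacement
continuity, no contact mechanics).  The static load is 100 N buccolingual
plus 250 N intrusive (resultant ≈ 269 N at ≈ 68° to the occlusal plane),
applied without eccentricity on the abutment top, 7 mm above the outer bone
surface.  A point load on a continuum is singular, so the load enters as a
statically equivalent uniform traction over a 0.5 mm patch; by Saint-Venant's
principle the choice is immaterial in bone.

Bone overload risk is judged pointwise from the principal stresses
$\sigma_1 \ge \sigma_2 \ge \sigma_3$:

$$\sigma_C = \min(\sigma_1,\sigma_2,\sigma_3,0), \qquad
  \sigma_T = \max(\sigma_1,\sigma_2,\sigma_3,0),$$

$$R = \frac{|\sigma_C|}{\sigma_{C0}} + \frac{\sigma_T}{\sigma_{T0}} \le 1,$$

with admissible limits $\sigma_{T0}=180$, $\sigma_{C0}=115$ MPa for cortical
bone and $5$ MPa for both in trabecular bone.  $R > 1$ flags a locally
critical state.  The Von Mises stress serves as a sign-blind global
indicator.  Statistics (volume-weighted mean and peak) are reported over a
control volume: the bone layer within $\delta = 0.25\,D$ of the implant
surface, split into the cortical part $\Omega_c$ and three trabecular
subregions of equal axial length (crestal, intermediate, apical), separated
by two planes orthogonal to the implant axis.

## Geometry

`implantCatalogue()` returns eleven parametric implants: ten bevelled,
helically milled designs spanning $D \in \{3.6, 4.3\}$, $L \in \{5.5, 9\}$ mm,
saw-tooth (T0/30) or trapezoid (T10/30) two-start threads with effective
pitch 1.2 mm and depths 0.38/0.38 (ST) or 0.38/0.19 mm (DT), small or large
milling, plus a commercial-style stand-in "A" ($D=3.5$, $L=11$, no milling).
The abutment connection diameter defaults to $0.75\,D$ (platform switching).
Threads are realized as circumferential annular fins with the exact 2D
profile by default; a true two-start helical sweep is available.  The
flank-angle convention follows the thread names: the coronal flank is 120°
from the implant axis for both profiles, the apical flank is axially flat
for the saw-tooth and 100° from the axis for the trapezoid.

The bone segment is synthetic: an idealized premolar section (trapezoid,
8 mm crest width flaring to 11 mm over a 14 mm height, 40 mm mesiodistal
span) with a 2 mm cortical shell around a trabecular core.  Interior corners
where two cortical plates meet are rounded with a 1 mm fillet: real
corticalization is graded, and a sharp interior bi-material corner would be
a spurious stress singularity.  Placement codes P0/P05/P1 put the platform
0/0.5/1 mm below the crest.  Subcrestal placements carry crestal bone up to
the outer surface, covering the platform ledge (the lead-in bevel, modelled
as a steep chamfer from the connection diameter to the collar); a soft-tissue
gap of 0.2 mm, flaring coronally at 0.7 mm/mm, separates the abutment wall
from bone, since the implant–abutment junction is not osseointegrated.
Crestal placements may carry a marginal-bone-loss crater: an axisymmetric
cone of depth `bone_loss_fraction` × cortical thickness with a 45° wall.
Milling flutes fade to zero depth over the coronal quarter of the threaded
span, as ground flutes do not reach the collar.

## Meshing

There is no tetrahedral mesh generator available to R in this environment,
so the package ships a purpose-built mapped mesher: a polar ring template
(centre fan plus graded rings) is extruded along the implant axis; node
radii are fitted to the implant/abutment radius function so the
bone–implant interface is an exactly body-fitted node surface; prisms are
split into tetrahedra with a global-minimum-vertex diagonal rule, which
guarantees a conforming mesh; mid-edge nodes sit at straight-edge midpoints
(subparametric elements).  Mesh layers snap onto the platform level, the
cortical–trabecular horizon, the floor plate and the implant apex so that
material interfaces are clean.

The size field is two-zone: $h_i = 0.05\,D$ near the interface (radially)
and $h_0 = 0.1\,D$ beyond a transition of $0.3\,D$, growing to $2 h_0$ in
the far support region.  Axial spacing is capped at half the thread fin
spacing so the thread never aliases, and the crestal band (cortical plate
plus 1 mm) is sub-refined to half the thread's free thickness, where the
reported peaks live.  The mesh is deliberately anisotropic (angular spacing
up to a few times the radial size): the stress field varies smoothly in the
angular direction, and quadratic elements tolerate the aspect ratio.  The
quality gate therefore uses a low floor (0.005 on the normalized-volume
metric) and rejects only genuinely degenerate meshes; isotropic calibration
meshes (`meshBox`, `meshTube`) hit their mean-edge targets within 25%.

Geometry and load are mirror-symmetric about the buccolingual plane
(annular threads, axisymmetric crater/apposition/gap; the helical milling
groove is minor and symmetrized), so by default only the $y \ge 0$ half is
meshed, with $u_y = 0$ on the symmetry plane and half the load applied.
This halves the direct-solver cost, which is what bounds the attainable
resolution.

The solved subdomain is a peri-implant cylinder (default radius: half the
crest width + 1.25 mm, so the buccal/lingual plates remain free surfaces)
over the full section height plus abutment; its outer lateral and bottom
surfaces carry the fixed `coronal_cuts` support standing in for the remote
mesiodistal cuts of the full 40 mm segment — legitimate for near-implant
comparisons by the same Saint-Venant argument that justifies fixing the
remote cuts in the first place.

## Solution and error control

Assembly uses a pure displacement formulation with 4-point quadrature per
tet10 (compiled kernels), solved by sparse supernodal Cholesky — fully
deterministic.  Verification: the patch test is exact to machine precision,
a uniaxial bar matches $FL/EA$, and the thick-walled (Lamé) cylinder
converges to the closed form (≤ 2% RMS stress error at the second
refinement level).

`recoverStress()` builds nodal stresses region by region (never averaging
across material interfaces, where the true stress is discontinuous), either
by volume-weighted averaging or by superconvergent patch recovery (linear
least-squares per nodal patch, exact for linear fields).
`energyErrorNorm()` is the recovery-based estimate
$100\sqrt{E_{err}/(U^\ast + E_{err})}$; `displacementErrorNorm()` is the
relative $L_2$ change between successive refinements, with the coarse
solution interpolated onto the fine quadrature points (a "displacement
error norm" is not a single-mesh quantity; the successive-refinement
reading is the one adopted here).  `convergeMesh()` walks a $h_i/D$ schedule
and certifies a mesh when its energy norm and the displacement change to
its next refinement pass the thresholds (defaults 5% and 0.5%).

Two desk-scale caveats, demonstrated honestly by the bundled studies: the
published 5%/0.5% thresholds were achieved at $h_i/D = 0.01$, an order of
magnitude finer than what a single-core direct solve accommodates, and the
mapped mesher re-discretizes the thread surface at every level, so the
displacement change between levels mixes geometry refinement with FE error.
On fixed-geometry benchmarks the estimator converges at the expected rate;
on scenario meshes the certification is reported with `converged = FALSE`
and the honest norms.

## Study conventions

`solveScenario()` reports region statistics on the region-wise recovered
nodal field interpolated back to the Gauss points.  This mirrors how
commercial FE postprocessors report nodal-averaged contour data — the form
in which peak stresses are conventionally read — and it is far less
sensitive to
single-Gauss-point noise at coarse resolution; raw-Gauss statistics remain
available (`stress_field = "raw"`, and `regionStats()` itself is
field-agnostic).  Peaks are maxima over member Gauss points; means are
volume-weighted (quadrature weight × Jacobian).  Percent changes between
scenarios use the first-named (worse) scenario as reference:
$100\,(a-b)/a$.

The three bundled studies are: the eleven-implant design sweep at P1 with
0.25 mm apposition; the positioning comparison P0 (with a 10% bone-loss
crater, the convention for crestal results) versus P05/P1 for implants 8
and A; and the marginal bone-loss sweep at P0 over crater depths 0–50% of
the cortical thickness.  Study-level meshes use $h_i/D = 0.05$ (about
25–35k quadratic tets per half-domain scenario); the convergence study uses
a reduced peri-implant domain (radius 2.8 mm, 12 angular divisions) so the
finest schedule level stays solvable.

## What the synthetic bone does and does not represent

The generator reproduces the section dimensions, shell thickness, material
contrast and crestal morphologies of a premolar segment, which is enough
for *relative* statements (design A versus design B on identical bone).  It
does not reproduce patient-specific anatomy: cortical thickness variation,
trabecular density gradients, the curved sinus floor, or the exact ridge
shape.  Absolute stress values therefore differ from any specific-patient
computation, and narrow features of the synthetic ridge (the ~0.4 mm
trabecular corridors between a 3.6–4.3 mm implant and 2 mm buccal plates)
concentrate trabecular stress more than a real, graded anatomy would.
Passing trend tests here supports the comparative conclusions, not absolute
safety margins.

The synthetic-CT module voxelizes the same analytic bone model around class
means of 0 / 400 / 1200 HU (invented; only the 150 and 750 HU segmentation
thresholds are fixed by convention) plus Gaussian noise, and the threshold
segmentation reproduces the generating masks exactly in the noiseless case.
It stands in for the scan-to-model pipeline; the FE path takes its geometry
from the parametric model, not from voxels.

## Numerical choices and degenerate inputs

Direct solver, relative residual checked at $10^{-8}$; eigenvalues of
stress tensors by the closed-form trigonometric solution (guarded for the
hydrostatic case, cross-checked against `eigen()`); point-to-surface
distances by exact point-triangle distance against the triangulated
interface with a brute-force oracle in the tests.  Degenerate inputs are
refused with named constraints: self-intersecting thread profiles, shells
thicker than half the crest, implants whose apex exits the cortical floor,
apposition at crestal placement or craters at subcrestal placement, empty
face groups, and unconstrained (singular) systems.  A thread depth of zero
degenerates cleanly to a smooth cylinder.  Empty control regions are
flagged, never silently zeroed.

## Known limitations

Bone is dry, isotropic, homogeneous per region and time-independent; no
contact or friction (full osseointegration); no muscle–jaw interaction,
dynamics, or remodeling.  The mesiodistal far field is truncated to a
cylinder; milling is symmetrized under the half-domain default.  Peak
statistics at bi-material corners are mesh-sensitive in any FE model;
the recovered-field convention damps but does not eliminate this.
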