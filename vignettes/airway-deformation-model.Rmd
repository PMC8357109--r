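---
title: "The pivotal-plane airway deformation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pivotal-plane airway deformation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaydeform)
```

## The planning problem

Maxillomandibular advancement (MMA) surgery moves the maxilla and mandible
forward to enlarge the upper airway of obstructive-sleep-apnea patients.
Planning the advancement would benefit from knowing, before surgery, what
the pharyngeal airway will look like afterwards: the predicted geometry can
be meshed and run through a CFD solver, and its cross-sections and pressure
drops compared with rhinomanometric measurements. `airwaydeform` implements
the geometric core of that workflow: a smooth, surgeon-parameterized
deformation of a CT-derived airway surface, cross-section dimensioning, an
inverse fit to target postoperative dimensions, and the small amount of
measurement calculus around it (nasal resistances, grid-refinement
assessment, CFD case metadata). Flow solving itself is out of scope.

All lengths are millimetres in the CT patient frame: x right-to-left,
y face-to-back (+y is the spine side), z foot-to-head.

## The displacement field

Three pivotal planes orthogonal to the z axis are placed at anatomical
levels — typically the nasal confluence, the tip of the soft palate and the
tip of the epiglottis — with heights $z_l < z_m < z_t$. Two regions are
held fixed exactly: everything at or above the top plane ($z \ge z_t$), and
everything at or behind the spine-side pharynx wall ($y \ge Y_s(z)$). The
middle and lower planes each carry an anteroposterior enlargement $dY_i \ge
0$ and a half-to-peak lateral enlargement $dX_i \ge 0$; the surgeon derives
these from the planned bone movements (a total lateral widening of 2 mm is
entered as $dX = 1$; see `lateral_half_enlargement()`).

The field is a combination of quadratic polynomials chosen so that the
displacement has continuous first derivatives everywhere, is linear in the
parameters, and achieves the prescribed enlargements *exactly* at the
control points of each controlled plane:

* **Axial profiles.** Each controlled plane has a cardinal basis $B_i(z)$
  with $B_i(z_i) = 1$, $B_i(z_j) = 0$ on the other controlled plane, and
  value and slope zero at $z_t$; below $z_l$ profiles continue with their
  lower-plane value. Then $dY(z) = \sum_i B_i(z)\,dY_i$, and likewise
  $dX(z)$.
* **Anterior displacement.** $\Delta y = -dY(z)\, W(y)$ with
  $W(y) = ((Y_s - y)/(Y_s - Y_c))^2$ for $y < Y_s$ and $0$ beyond, where
  $Y_c(z)$ is the anterior (minimum-y) extreme on the mid-sagittal line.
  $W$ equals 1 at $Y_c$, so the anterior wall moves forward by exactly
  $dY$, and it reaches zero with zero slope at $Y_s$, so the spine side is
  C1-fixed. Because $W$ is monotone on the lumen, the depth $Y_s - Y_c$
  grows by exactly $dY$ at the plane.
* **Lateral displacement.** $\Delta x = dX(z)\, S(x)\, F(y)$ with
  $S = \operatorname{sign}(x - x_c)\min(1, ((x - x_c)/w_{half})^2)$:
  zero (with zero one-sided slopes) at the mid-sagittal line $x_c$, and
  $\pm 1$ at the lateral extremes, so the width grows by exactly $2\,dX$.
  $F(y)$ is a C1 falloff that is 1 at and below the section's widest
  level and 0 at $Y_s$, again fixing the spine side.
* $\Delta z = 0$ everywhere.

### Why the quadratic splines have an interior knot

A single quadratic piece per inter-plane interval cannot satisfy all the
constraints at once: a cardinal axial basis needs prescribed values at both
interval ends *and* prescribed slopes there (zero slope at $z_l$ so the
constant extension below stays C1; a matched slope at $z_m$), which is four
conditions on a three-parameter polynomial. Each interval therefore uses
two quadratic pieces joined C1 at the interval midpoint — the unique
quadratic Hermite spline for the endpoint data. The same construction
interpolates the per-plane anatomy ($Y_s$, $Y_c$, $x_c$, $w_{half}$, widest
level) across $[z_l, z_t]$ with zero end slopes, so the clamped extensions
above and below are C1 too. The field is consequently piecewise-polynomial
of low degree in every direction, and the tests verify the C1 property with
one-sided second-order finite differences on a 0.1 mm grid (jumps below
$10^{-3}$).

The lateral term deserves one more remark. A falloff anchored like $W$ at
$Y_c$ would scale the widening at the widest level (where width is
measured) by roughly $((Y_s - y_w)/(Y_s - Y_c))^2 \approx 1/4$ on an
ellipse, breaking the exact-width property. The implemented $F$ is instead
1 *with zero slope* at the widest level, which both preserves C1 smoothness
and makes the maximum-width increase exactly $2\,dX$ on convex sections.

### Anatomy estimation and degenerate inputs

$Y_s$ and $Y_c$ can be supplied per plane (as in a surgeon's parameter
table) or estimated from the preoperative mesh; $x_c$, $w_{half}$ and the
widest level are always estimated, via `estimate_plane_anatomy()`, from the
largest-area contour of the slice at the plane. The largest-contour rule is
the tie-break for multi-contour (nasal-level) slices; the deformation is
intended for the single-lumen pharyngeal region below the confluence.
$Y_c$ is taken over contour points within 0.5 mm of the mid-sagittal x — a
band wide enough to be robust to contour discretization and narrow enough
not to drift off the midline. Slices exactly through mesh vertices use the
standard symbolic perturbation (a vertex at the plane is treated as
$10^{-9}$ mm above it), and slice assembly is tolerance-free: intersection
points are computed once per crossing mesh edge, so adjacent facets share
loop endpoints bit-for-bit, and any open chain (non-watertight mesh) is
reported as an error with the gap size.

## Inverse fitting (follow-up prediction)

`fit_deformation()` chooses parameters so the deformed geometry matches
target postoperative dimensions at the controlled planes. For width targets
the update is the undamped difference step
$dY \leftarrow dY + (\text{target depth} - \text{achieved depth})$ and
$dX \leftarrow dX + (\text{target width} - \text{achieved width})/2$;
because the field responds linearly and exactly at the control points, this
converges in one step up to discretization, and the iteration in practice
stops after two passes (the second confirms the residual). Area targets
respond nonlinearly, so the plane's $(dY, dX)$ pair is scaled jointly by
the damped factor $1 + \tfrac12(\sqrt{A_{target}/A_{achieved}} - 1)$, with
an initial seed from proportional growth of the preoperative section. All
target planes are fitted simultaneously; parameters are clamped at zero
(the model only enlarges), and an unreachable target ends with
`converged = FALSE` rather than an error. Default tolerances are 0.05 mm
per width and 0.5% relative area.

## The synthetic airway

Patient CT surfaces cannot be redistributed, so the package ships a
parametric surrogate (`airway_spec()` / `generate_airway()`): an elliptical
pharyngeal tube with smooth semi-axes $a(z)$, $b(z)$ and centerline offset
$c(z)$ — default a constant $a = 10$, $b = 6$ mm ellipse over z = 0–80 mm —
joined at the confluence plane by two circular nasal tubes (radius 3.5 mm,
offset ±7 mm, 20 mm long). Every cross-section is analytically known
(`analytic_cross_section()`: area $\pi a b$, $Y_s = c + b$, $Y_c = c - b$),
which gives the slice pipeline an exact oracle: at 64 vertices per ring the
inscribed-polygon area deficit is about $6.6/n^2 \approx 0.16\%$, at 256 it
is below 0.01%, matching the 1% / 0.1% acceptance bands. The three
components are each individually watertight (every edge shared by exactly
two facets); they meet at, but are not merged across, the confluence plane.
This is deliberate: all downstream quantities are per-slice contour
metrics, for which a blended bifurcation adds complexity without changing
any number. Angular resolutions divisible by 4 place vertices exactly at
the section extremes, which keeps width/depth measurements crisp. The seed
affects only optional uniform radial noise (default 0) used to exercise
smoothing; the geometry itself is deterministic.

What the surrogate does *not* emulate: turbinates, paranasal sinuses,
non-convex lumen shapes, and surface corrugation of real segmentations.
Passing tests therefore demonstrate the correctness of the geometric
operators and the model's contract, not segmentation robustness on
clinical STL files.

## Geometry I/O and smoothing

STL (ASCII and binary) is read and written natively. STL stores facets
independently, so corners are merged into shared vertices with a fixed
$10^{-6}$ mm grid-snap tolerance — connectivity is required by smoothing
and slicing. Normals are recomputed from vertex winding on write; stored
normals are never trusted. Binary STL uses float32 per the standard, so
round-trip fidelity is relative (about $10^{-7}$); the $10^{-6}$ mm
absolute round-trip guarantee is tested at unit scale.

Real segmentations are corrugated by digitization artifacts and need
smoothing before meshing. `smooth_mesh()` uses two-step neighbor averaging
with a shrink-compensating negative back-step (Taubin's lambda–mu scheme,
$\lambda = 0.33 s$, $\mu = -0.34 s$ for strength $s$): plain Laplacian
smoothing shrinks the lumen and would bias cross-section areas, whereas
the back-step keeps slice areas of a clean tube within 1% over ten
iterations while still contracting radial noise.

## Respiratory metrics

Anterior-mask rhinomanometry measures one naris at a time: with the other
naris plugged (and used as a static-pressure tap), the resistance is
$R = (P_1 - P_2)/F$. The two passages act in parallel between shared
pressures, so the total is $R_L R_R/(R_L + R_R)$; a fully blocked naris
($R \to \infty$) correctly degenerates to the open side. Resistance is
read off a pressure–flow curve by linear interpolation of flow at a
reference pressure difference, defaulting to 100 Pa — the international
anterior-rhinomanometry convention — since raw curves do not by themselves
define a single resistance value.

`assess_refinement()` encodes the usual engineering rule for pressure-drop
mesh independence: take the finest mesh as reference and recommend the
smallest cell count whose pressure difference lies within a relative
tolerance of it, default 10%. The tolerance is exposed, and the
recommendation is monotone in it. `cfd_case_spec()` records the breathing
at-rest boundary conditions (ambient 1.013e5 Pa, 25 °C, viscosity
1.822e-5 Pa·s, mass-flow inlet, static-pressure outlet, residual < 1e-6 or
mass-flow imbalance < 0.5%, near-wall y+ in 2–5) purely as exportable
metadata.

## Problem sizes and numerical defaults

The test and acceptance workloads use the default surrogate (64 vertices
per ring, 0.5 rings/mm: about 3.3k vertices and 6.7k facets), which is
ample for the contour metrics — the dominant error is the $O(n^{-2})$
polygon inscription, not mesh density. The vertex-merge tolerance is
$10^{-6}$ mm, loop-closure is exact by construction, degenerate facets are
defined by area $\le 10^{-12}$ mm², and the achieved-enlargement checks
use a 0.05 mm band, which absorbs the chord error of sampling the
quadratic axial profile between mesh rings (about 0.01 mm at the default
ring spacing).

## Known limitations

* The deformation is purely geometric: the mapping from bone movement to
  $(dY, dX)$ is supplied by the surgeon, and no soft-tissue mechanics is
  modelled.
* The spine-side wall is held fixed by construction, so predicted contours
  can differ from postoperative ones around the spine side even when
  widths or areas match; contour *shape* is not a fitting target.
* Lateral widening is symmetric about the mid-sagittal line; there is no
  asymmetric option.
* Only horizontal (constant-z) planes are supported for slicing and
  control; oblique or curved-centerline sections are out of scope.
* Below the lowest pivotal plane the displacement is clamped to its
  lower-plane value, keeping the outlet section consistent; points there
  move as much as the lower plane does.
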