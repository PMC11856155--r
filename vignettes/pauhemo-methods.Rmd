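---
title: "Models and methods behind pauhemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pauhemo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pauhemo)
```

`pauhemo` compares, on synthetic thoracic-aorta geometries, the hemodynamic
footprint of two treatments for penetrating aortic ulcer (PAU) that both
require managing the left subclavian artery (LSA): a single-branched stent
graft (SBSG) that keeps the LSA perfused through an integral branch but
narrows its origin, and a hybrid repair that covers the LSA origin entirely
and re-perfuses it through a surgical carotid–subclavian bypass. This
vignette records the models the package implements, the defaults it chooses,
and the reasoning behind the choices that were genuinely open.

## The synthetic aorta generator

Clinical analyses of this question start from CT angiography. No imaging is
bundled here; instead `make_aorta()` builds parametric thoracic aortas with
exact, analytically known geometry, so every downstream measurement can be
validated against ground truth rather than against another mesh tool.

The vessel is modelled as an implicit solid: ascending segment (capsule),
arch (circular-arc tube of radius 30 mm by default), linearly tapered
descending segment, and up to three supra-aortic branches (capsules leaving
the arch at prescribed arc positions and angles). The three treatment
configurations differ only in the LSA:

* **PRE** — nominal branch, optional saccular PAU bulge (a sphere union on
  the outer wall);
* **SBSG** — the proximal 15 mm of the exposed LSA is reduced in diameter by
  the fraction `lsa_narrowing`, with a 4 mm conical transition back to
  nominal;
* **HYBRID** — the proximal LSA is removed entirely (the arch wall closes
  over the ostium by construction of the implicit union) and a curved 8 mm
  conduit (a quadratic Bézier tube bowing 12 mm out of the arch plane) joins
  the mid LCCA to the LSA 2 cm beyond its origin.

The union of signed-distance primitives is polygonised by marching
tetrahedra on a regular grid (six tetrahedra per cube sharing the main
diagonal, so crossing points on shared cell edges coincide exactly). This
guarantees a closed, manifold triangulation for any parameter combination
that passes the branch-collision check — the reason this route was chosen
over boolean surface unions, which require a remeshing engine to restore
watertightness. Triangle winding is made globally consistent by propagating
orientation across shared edges and fixing the sign with the enclosed
volume. The default grid spacing (`mesh_resolution = 1.6` mm for standalone
use, 1.8 mm in the bundled study configuration) resolves the smallest branch
radius (~4.5 mm) with roughly three cells; geometric errors of the
polygonisation are second order in the spacing, about 0.05 mm on the branch
radii.

Default dimensions (inlet diameter 26 mm; branch diameters 13/9/11.5 mm at
arch positions 55°/85°/112°, angles 75°/82°/87°; 0.9 descending taper) are
typical adult values; they are a modelling choice, not a patient
reconstruction. The only randomness in the generator is a sub-cell jitter of
the sampling grid and the optional magnitude jitter of synthetic
wall-shear-stress fields, both drawn from the seed carried in the spec.

Each generated vessel records exact parametric centerlines, branch angles,
tortuosities, outlet areas and a segment skeleton (lengths and diameters of
every vessel piece, including the narrowed LSA origin or the bypass). The
recorded `truth_angles` are the angles between the branch axis and the local
aortic *tangent* — the quantity the spec of the geometry fixes. The measured
bifurcation angle (below) uses chord vectors of finite length, which on a
curved arch differs from the tangent angle by construction; validation of
angle recovery therefore uses straight-main-vessel geometries
(`arch_sweep_deg = 0`), where chord and tangent coincide.

## Morphometry

`compute_centerline()` extracts lumen centerlines by centroid marching: cut
the surface with a plane orthogonal to the travel direction, re-centre on
the local lumen, advance one step, smooth the travel direction. The
re-centring uses an iteratively trimmed least-squares circle fit to the
section perimeter rather than the raw polygon centroid: where the cut plane
spans a branch ostium the intersection polygon merges with the neighbouring
vessel and its area centroid is meaningless, while the circle fit (seeded by
a running radius estimate, trimming residuals in four passes) stays locked
to the local lumen; if even the fit is dominated by a merged structure the
front coasts one step on its current heading. On a clean torus-segment tube
the extracted line stays within about 1% of the tube radius of the true
parametric circle.

`extract_sections()` cuts planes orthogonal to the centerline tangent at
uniform stations and measures each closed intersection polygon: area by the
shoelace formula (reported in cm²) and maximum diameter as the largest
pairwise distance over the perimeter resampled at 0.2 mm (reported in cm;
the resampling removes tessellation bias, and the diameter is evaluated on
the convex hull where it is attained). Stations whose cut is open are
skipped with a warning; stations straddling the ostium, recognisable by a
diameter far above the branch profile, are trimmed from branch summaries.

The bifurcation angle follows the two-chord convention: the branch vector
runs from the first branch-centerline point over an arc distance equal to
the branch diameter (by default the first section's maximum diameter), and
the aortic vector runs from the aortic point nearest the branch origin over
the same arc distance towards the descending aorta. Tortuosity is reported
as arc length over endpoint chord minus one — zero for a straight vessel,
π/2 − 1 ≈ 0.571 for a semicircle — with the raw ratio available via
`index = "ratio"`; the excess form was chosen because it makes "straight"
read as 0 and matches the magnitude range of clinical centerline-tortuosity
indices.

## Windkessel outlets

Each outlet is terminated by a three-element Windkessel: proximal resistance
`Rp`, distal resistance `Rd`, compliance `C`, with outlet pressure obeying

P + Rd·C·dP/dt = (Rp + Rd)·Q + Rp·Rd·C·dQ/dt.

`solve_rcr()` integrates this cycle by cycle until the maximum
cycle-to-cycle pressure change is below 0.06%, the same periodic-steady-state
criterion used for the network solver, and returns the last cycle. The
default step is an integrating-factor (exponential) scheme with the solver
nodes aligned to the waveform samples; because the forcing is piecewise
linear between samples, the step is then exact up to the interpolation of
the waveform itself, and agreement with an adaptive high-order reference
integration is well inside 0.1%. A Crank–Nicolson and a backward-Euler step
are kept as options; the first-order step was measured at ~0.3–1% error at
dt = 0.004 s, which motivated the stronger default. `dQ/dt` uses centered
periodic differences at the waveform samples, since the equation contains
the flow derivative explicitly.

`calibrate_rcr()` matches prescribed systolic/diastolic pressures by a
damped two-variable fixed point: the total resistance is updated from the
mean-pressure proxy (p_sys + 2·p_dia)/3 (used only to steer; convergence is
judged on the extrema themselves), and the compliance from the pulse
pressure, with exponent 0.7 damping. The proximal fraction
γ = Rp/(Rp + Rd) is held fixed during calibration — the split is not
identifiable from two pressure extrema alone — with default γ = 0.09, the
value implied by the packaged reference parameter sets, whose distal/proximal
ratio is ≈ 11 at every outlet. Pulse-pressure targets outside the range
achievable for any compliance at the given γ (bracketed by simulating the
near-zero and near-infinite compliance limits) abort with the achievable
bounds. A pulseless waveform leaves `C` unidentifiable; it is returned at
its initial value and flagged.

`distribute_rcr()` splits a calibrated global load over the outlets by area
ratio — resistances scale with Atot/Ai, compliance with Ai/Atot — so the
parallel combination recovers the global load exactly and the distal time
constant Rd_i·C_i is the same at every outlet. `validate_rcr_table()` checks
precisely these structural consequences on any per-outlet table and flags
outlets that violate them; on the packaged three-case reference table it
flags one compliance cell (first case-3 outlet) whose distal time constant
is ~34% away from the other three outlets of its case, a value the area-ratio
structure cannot produce and which the package therefore reports rather than
reconciles.

## The lumped network stand-in

The full 3D finite-volume solve that a CFD study would run is out of scope;
in its place `solve_network()` solves a 0D resistive network assembled from
the generator's segment skeleton: one Poiseuille resistance
R = 128·μ·L/(π·D⁴) per vessel piece (blood at density 1060 kg/m³ and
viscosity 3.5×10⁻³ Pa·s), single-valued junction pressures, prescribed
inflow at the inlet, and the distributed RCR loads at the terminals
(advanced by an implicit Euler step and eliminated into the nodal system,
which is factorised once per run). Flow conservation at junctions holds to
the accuracy of the linear solve (≲10⁻¹² relative).

This stand-in is deliberately minimal: no inertance, no nonlinear stenosis
loss, no wave propagation. It targets the *ordering* of configurations —
LSA flow PRE ≥ SBSG > HYBRID, arch→LSA pressure drop PRE < SBSG < HYBRID —
and the monotone response to origin narrowing (a D⁻⁴ law), not absolute
magnitudes. The flow decrements it produces for the default geometries are
roughly an order of magnitude smaller than patient-specific 3D values,
because a 12% diameter narrowing barely perturbs a branch whose impedance is
dominated by its distal Windkessel; the 3D effects (jet losses, recirculation)
that amplify the clinical difference are exactly what the stand-in omits.
The reported pressure drop is taken between the LSA take-off junction on the
arch (retained as a pass-through node in the HYBRID network) and the LSA
outlet node, at the systolic peak defined as the instant of maximum inlet
flow.

The inflow is a parametric waveform — a half-sine systolic ejection filling
35% of the 0.85 s cycle, followed by a brief 5%-amplitude early-diastolic
reversal — scaled so its periodic trapezoidal integral equals the stroke
volume (70 mL by default) exactly. The shape is a stylised adult aortic flow
profile; its parameters are exposed because no specific patient waveform is
emulated.

## Wall-shear-stress indicators

From a per-node WSS vector series over one cycle, the package computes
TAWSS (time-averaged WSS magnitude), OSI
(0.5·(1 − |∫WSS dt| / ∫|WSS| dt), 0 for a fixed direction and 0.5 for a
perfect equal-duration reversal) and ECAP (OSI/TAWSS). Integrals use the
periodic trapezoidal rule, which for uniform full-cycle sampling reduces to
dt·Σ — this makes the OSI of an exactly reversing signal equal to 0.5 to
machine precision rather than approximately. Nodes where ∫|WSS| dt falls
below 10⁻¹² Pa·s are masked in OSI, and TAWSS below 10⁻⁶ Pa masks ECAP;
masked nodes are excluded from area statistics.

Exposure statistics mirror the clinical thresholds: wall-area fraction with
TAWSS < 0.4 Pa (atherosclerosis-prone) and with OSI > 0.25 (atherogenic),
using strict inequalities so threshold ties are excluded. Triangles are
classified by the mean of their three vertex values; the alternative
(vertex-lumped area weighting) changes results only at the mesh-resolution
scale. No ECAP area threshold is applied — literature cut-offs vary and the
map itself is the deliverable.

Because the package does not run a 3D solve, WSS fields are synthesised by
`make_wss_field()`: per node a tangential direction, a magnitude and a
reversal fraction α define a square-reversal signal whose TAWSS and OSI have
closed forms, returned alongside as ground truth (OSI is zero for α ≤ 0.5 —
the signal never changes sign — and (2α−1)/(2α) above). The study pipeline's
default spatial patterns put lower magnitudes and stronger oscillation
towards the distal arch and proximal descending aorta, emulating the
low-TAWSS/high-OSI pockets reported after arch interventions; they are an
emulation of spatial structure, not of any specific case.

## Pipeline, determinism and problem sizes

`run_study()` chains the stages (generate → morphometry → calibrate →
distribute → network comparison → indicator maps → report) under one
validated configuration with a strict schema; a single integer seed drives
every random draw, and re-running the same configuration reproduces the JSON
reports byte for byte. The manifest records the package version, seed and an
MD5 hash of the scientific configuration (the output directory is excluded
from the hash). The bundled defaults — 1.8 mm grid, 2 mm section spacing,
0.004 s time step, 32 WSS time samples — keep a full three-configuration
study under half a minute on one core while leaving all measured quantities
comfortably inside their validation tolerances; halving the grid spacing or
the time step changes the reported quantities by well under 1%.

## What the validation does and does not show

The test suite validates every operation against analytic ground truth
(cylinders, cones, ellipses, torus tubes, closed-form Windkessel limits,
brute-force indicator oracles) and the pipeline against the generator's
exact truth. Passing these tests shows the *operations* are correct; it does
not show that the synthetic geometries span real anatomical variability,
that a 0D network predicts 3D flow magnitudes, or that synthetic WSS fields
resemble solver output. Real meshes additionally carry segmentation noise,
holes and non-circular lumens that the circle-fit re-centring handles only
up to a point; the marching diagnostics (lost tracking, open cuts) are
designed to fail loudly there rather than silently degrade.
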