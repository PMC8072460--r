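---
title: "Modeling portal venous hemodynamics around splenectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling portal venous hemodynamics around splenectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Splenectomy removes the dominant inflow of the portal venous system (PVS):
the splenic vein (SV) is ligated near the splenic hilus and the remaining
flow is supplied only by the superior and inferior mesenteric veins (SMV,
IMV) and the left gastric vein (LGV). The ligated SV becomes a dead-end
stump with near-stagnant blood. Low wall shear stress (WSS) promotes
endothelial dysfunction, platelet aggregation and fibrin deposition, so the
fraction of vessel wall exposed to low WSS is a mechanistic proxy for the
risk of portal venous system thrombosis, a frequent and serious sequela of
the operation.

`pvshemo` builds a family of idealized PVS geometries spanning the
anatomical variability reported in imaging studies, solves steady
incompressible flow of shear-thinning blood in them before and after
splenectomy, and summarizes the wall environment with two statistics:

* **SA-WSS**, the area-weighted mean of the WSS magnitude over the wall,
  $\mathrm{SA\text{-}WSS} = \frac{1}{A_W}\sum_i \mathrm{WSS}_i\,\Delta A_i$;
* **ALS**, the percentage of wall area exposed to WSS below a threshold
  $\tau_T$,
  $\mathrm{ALS} = \frac{100}{A_W}\sum_{i\,:\,\mathrm{WSS}_i<\tau_T}\Delta A_i$,
  with $\tau_T = 0.1$ Pa, a conventional low-WSS threshold for venous
  thrombosis.

The wall $A_W$ comprises the lateral vessel surfaces plus the ligated SV
cap (it is physical wall after surgery); open inlet and outlet port disks
are not wall. Faces exactly at the threshold are not counted in ALS (strict
inequality).

## Geometry family

The vessel tree is planar: the splenoportal junction sits at the origin,
the SV runs along +x toward the spleen, and the portal vein (PV) and SMV
leave the junction at 113 and 96 degrees to the SV. Baseline diameters and
lengths are arithmetic means of published clinical measurements
(`pvs_vessel_table()`): PV 13.42/71.7 mm, SV 10.12/113.5 mm, SMV
11.875/60.8 mm, LGV 6/50 mm, IMV 4.1/59.7 mm. The 29-degree tilt of the PV
against the vertical plane is retained as orientation metadata only:
gravity is not modeled, so an out-of-plane tilt cannot affect the steady
flow field, and a planar construction keeps the geometry mirror-symmetric
(a property the tests exploit).

Four anatomy types differ in where the two smaller tributaries drain:
type 1 IMV→SV and LGV→SV, type 2 IMV→SV and LGV→PV, type 3 IMV→SMV and
LGV→SV, type 4 IMV→SMV and LGV→PV. Morphogeometrical variations change one
scalar each: the IMV–trunk angle (70 ± 20 degrees), the PV–SV angle
(113 ± 10 degrees), the SV diameter (10.12 ± 2.625 mm, the mean of the
reported standard deviations), and the IMV distance from the splenoportal
junction (60 ± 20 mm). A curved variant replaces the straight 50-mm mid-SV
segment between the LGV and IMV (which requires the IMV moved to 80 mm) by
an S-curve of two 10-mm straights and three tangential arcs (two quadrants
of radius 10 mm, one semicircle of radius 15 mm), arc length
$20 + 25\pi \approx 98.5$ mm, distance factor 1.97.

A few positions are not reported numerically anywhere we could find and are
package decisions, exposed as configuration fields:

* the LGV-on-SV junction sits 30 mm from the splenoportal junction — the
  only placement consistent with both the 80-mm IMV position of the `D+`
  variant and the stated 50-mm LGV–IMV mid segment;
* the LGV–trunk angle reuses the 70-degree IMV reference;
* LGV-on-PV attaches 35 mm along the PV, IMV-on-SMV 25 mm along the SMV,
  both at 70 degrees, mid-vessel and away from ports.

Tributary centerlines terminate on the host axis, so the union of the
capsule-shaped tubes blends each junction smoothly; no additional fillet is
applied (none is specified quantitatively in the source material for this
geometry family, and the union is already smooth at the working
resolution).

```{r}
library(pvshemo)
cfg <- build_anatomy(1, c("D+", "curved"), "postoperative")
model <- build_curved_sv(cfg)
surf <- centerline_to_surface(model)
write_stl(surf, "curved_post.stl")
```

## Blood rheology

Portal venous flow is slow (wall shear rates of order 10–100 s⁻¹), so
shear-thinning matters. Viscosity follows the Carreau law
$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
[1+(\lambda\dot\gamma)^2]^{(n-1)/2}$ with the standard blood constants
$\mu_0 = 0.056$ Pa s, $\mu_\infty = 0.00345$ Pa s, $\lambda = 3.313$ s,
$n = 0.3568$, density 1060 kg/m³. In the stagnant stump
$\mu \to \mu_0$; on briskly perfused walls $\mu \approx 0.005$ Pa s. The
low-WSS and high-viscosity maps therefore co-locate, which the metrics
quantify with an area-weighted Jaccard overlap.

## Discretization and solver

The fluid domain is discretized on a uniform Cartesian staggered (MAC)
grid immersed in the analytic signed-distance field of the tube union; the
wall itself is carried by the triangulated surface (per-face areas, patch
labels), so area bookkeeping is tessellation-accurate rather than
voxel-accurate. Wall boundary conditions use subcell ghost coefficients:
each near-wall stencil leg is shortened to the actual wall distance along
that axis, obtained from the signed-distance field, and near-wall
shear-rate stencils are one-sided quadratics anchored at the subcell wall
position. This combination was chosen over a body-fitted
tetrahedral/prism-layer mesh because it is robust, trivially deterministic,
and allows the whole pipeline to live in compiled code without an external
mesh generator; its cost is a first-order representation of the wall
position, which is the dominant discretization error discussed below.

The steady state is reached pseudo-transiently with a SIMPLE-type scheme:

* point-implicit first-order upwind convection and variable-viscosity
  diffusion — both unconditionally stable, so the pseudo-time step is
  limited only by accuracy of the path to steady state, not stability;
* the implicit momentum factor is carried into a variable-coefficient
  pressure projection, making the converged solution independent of the
  pseudo-time step (a pure Chorin splitting would distort the steady
  momentum balance near walls);
* the pressure Poisson problem is solved by conjugate gradients
  preconditioned with a geometric multigrid built on the masked domain
  (Galerkin coarsening with piecewise-constant transfers, damped-Jacobi
  smoothing) — a few iterations per step;
* the Carreau viscosity is Picard-updated every few steps;
* inlets impose parabolic profiles in short plug regions, with the
  discrete flux normalized to the exact analytic value $\bar v \pi R^2$;
  the PV outlet is a fixed-pressure buffer (25 mmHg). Because only
  pressure differences act on an incompressible flow, the outlet level
  shifts the pressure field without changing velocities or WSS, and a test
  asserts exactly that.

A run starts from rest with a 0.2-s inlet ramp and is declared steady when
the monitored SA-WSS drifts by less than 0.1% and ALS by less than 0.05
percentage points over a trailing 0.5-s window (never before 1.5 s of
pseudo-time, and a cap of 4.5 s is recorded as non-convergence, not
silently accepted). Mass conservation is monitored as the mismatch between
the plug influx and the outlet efflux and stays at the projection
tolerance, orders below the 0.5% acceptance bound.

WSS is extracted on the true triangulated wall: at each face centroid the
velocity is sampled at 1.5 and 3 grid spacings along the inward normal,
the tangential profile is fitted by a quadratic through zero at the wall,
and the wall shear stress is $\mu(\dot\gamma_w)\,\dot\gamma_w$. The fit is
exact for parabolic profiles and was checked against the exact
generalized-Poiseuille (Rabinowitsch) solution for Carreau profiles across
the study's vessels; its bias is below about 2% except in the narrow IMV,
where probes reach a large fraction of the radius.

## Problem sizes and resolution choice

The shipped `desk` preset uses 0.7 mm spacing (about $10^5$ grid cells and
20–40 k wall faces per model; tens of seconds per scenario on one CPU).
The spacing was fixed by a refinement study on the baseline models: 0.7 mm
is the coarsest member of the 1.2/1.0/0.8/0.7-mm series for which one
further step changes SA-WSS by less than 2% (`mesh_convergence_report()`
re-certifies this in the test suite). Absolute convergence is slower than
this sequential criterion suggests — a 20% refinement beyond the preset
still moves SA-WSS by about 3%, a consequence of the first-order wall
representation — which is consistent with the desk-scale SA-WSS sitting
5–15% below values computed at 0.08-mm body-fitted resolution, and is why
quantitative agreement is asserted within bands (±20% on SA-WSS, ±5
percentage points on ALS) rather than at printed precision. The `paper`
preset records the 0.08-mm/0.05-mm resolution of high-fidelity body-fitted
reference setups; it is cluster-scale and not exercised by the tests.

## The reduced-order network model

`network_from_anatomy()` abstracts the same anatomy into directed segments
between junctions. With a single outlet, segment flows follow from mass
conservation alone, so junction pressure losses never need modeling. Each
segment's wall shear uses fully developed pipe flow: either the
Newtonian-profile approximation ($\dot\gamma_w = 8\bar v/D$, closed form)
or the exact generalized-Poiseuille solution obtained by inverting the
constitutive law in the Rabinowitsch integral (Gauss–Legendre quadrature
plus root bracketing; reduces to $8\mu\bar v/D$ exactly in the Newtonian
limit, which the tests assert to 1e-9). The segment-wise ALS sums lateral
areas ($\pi D L$, with the arc length for the curved segment) of
sub-threshold segments.

The network model is deliberately blind to junction disturbance,
developing flow and secondary (Dean) flows; several postoperative
scenarios differ only through segments whose fully developed wall shear
sits within 2% of the 0.1 Pa threshold (the IMV-fed SV conduit is at
0.1014 Pa), so the network assigns them identical ALS ("structural ties").
The concordance test between the network and the 3D pipeline therefore
checks sign agreement of scenario differences only where the exact-profile
network resolves a difference; tied pairs are uninformative by
construction, and the package documents rather than hides this limit of
the screening tool.

## What the synthetic geometry family does and does not capture

The generator reproduces the idealized study conditions: planar
centerlines, circular cross-sections, no taper, rigid no-slip walls,
steady inlet velocities (SV 8.89, SMV 5.02, LGV 7.8, IMV 8 cm/s —
population-averaged values for portal hypertension), and a splenectomy
modeled purely as capping the SV inlet at its full length. Real portal
systems are tortuous, tapered, elliptical in section, pulsatile (weakly),
and compliant; patient-specific thrombosis prediction would require
image-based geometry. Passing the test suite therefore demonstrates
faithful reproduction of the idealized sensitivity study — which
anatomical features make the post-splenectomy wall environment
clot-promoting — not predictive accuracy for an individual patient.

## Known limitations

* First-order wall representation: desk-scale SA-WSS is biased low by
  5–15% relative to body-fitted high-resolution references; ALS is much
  less sensitive because it thresholds a bimodal WSS distribution
  (stagnant stump vs perfused conduits), but scenarios dominated by
  near-threshold segments inherit a few percentage points of uncertainty.
* The momentum equation uses the $\nabla\!\cdot(\mu\nabla u)$ form of the
  viscous term; the transpose part vanishes for fully developed flow and
  is small elsewhere at these Reynolds numbers (of order 10–100, laminar).
* Convection is first-order upwind by default. A deferred-correction
  central blend is available (`solver_settings(central_blend = )`) but is
  not enabled by default: at desk resolution it destabilizes the
  high-inflow preoperative runs well before reaching a second-order
  benefit.
* The outlet pressure is a reference level only; portal pressure itself is
  not predicted.

## Running the study

```{r}
report <- run_study(study_matrix())     # 27 scenarios, ~10 min on one CPU
trend_checks(report)
export_tables(report, "out")
```

`scripts/acceptance.R` drives the same pipeline end to end and writes the
headline quantities (maximum preoperative ALS, the postoperative ALS range
and headline scenario values, and the pre/post change of peak near-wall
viscosity in the SV) as JSON.
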