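---
title: "Models and methods behind trapflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trapflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trapflow` models biofilm-relevant hydrodynamics in a shallow (15 µm)
microfluidic channel decorated with partial-height microstructures, and the
fluorescence-microscopy analysis chain used to observe it. This vignette is
the package's account of the science: the models, their assumptions, the
tunable parameters, and what the synthetic data do and do not establish.

## Operating regime

All defaults describe a 5 mm wide, 15 µm high straight channel run at 0.5 or
3.0 µL min⁻¹ of water (ρ = 1000 kg m⁻³, µ = 1 mPa s; round values are
accurate to a few percent at ambient temperatures). The mean velocity is
U = Q/(wh) ≈ 111 or 667 µm s⁻¹, so Re = ρUL/µ is 0.003–0.02 with the
hydraulic diameter and about 0.001–0.01 with the 10 µm feature height: deep
creeping flow. Because a common Reynolds-number value can hide either length
convention, `reynolds_number()` takes the characteristic length as an
explicit argument rather than guessing. Stokes flow is linear in the pump
rate; several package invariants (velocities ×6, vorticity ×6, Q-criterion
×36 between the two rates) follow from that and are tested exactly.

## Geometry

Features are rasterized into a clearance map h(x, y): h equals the channel
height over open floor and `channel height − feature height` (5 µm) over
walls — features reach 2/3 of the channel height and flow passes over them.
Coordinates: x downstream, y across, z up; the raster stores row = y with a
documented flip to image space. Default cell size is 2 µm (≥ 10 cells across
a 20 µm wall).

The microtrap's funnel internals are not fully constrained by the published
footprint, so two internal parameters are exposed with declared defaults:

* `funnel_gap_width = 5` µm — the opening at each funnel apex. A cell-scale
  opening is consistent with the trap's purpose (retaining bacteria-sized
  objects) and with the low interior velocities this trap type exhibits.
  A wide (≳ 20 µm) aligned gap would leave a straight open lane through the
  trap with the same depth-conductivity as the open channel, which
  contradicts both.
* `funnel_half_angle = 60`° — the chevron arm angle. Six walls spread over a
  410 µm footprint leave inter-funnel cavities of ~35 µm at 60°, wide enough
  that cavity-center colonies are geometrically distinct from wall-adherent
  ones; at 45° the cavities narrow to about one wall thickness and the two
  localization modes collapse onto each other, which the imaging analysis
  (and the observed distinct regimes) requires to be separable.

Cavity regions are defined topologically: connected open regions inside the
footprint, with apex gaps sealed, that do not reach the upstream/downstream
edges. The constructor guarantees five of them for all rasters at ≤ 5 µm
cells, labels them in downstream order, and records cavity centers and
wall-junction "corner" points as metadata consumed by the transport and
quantification modules.

## Flow models

**Plan view (Hele-Shaw).** In a thin gap the depth-averaged flow obeys the
lubrication model ∇·(h³∇p) = 0, u = −h²/(12µ)∇p. The solver is a
cell-centered conservative finite-volume scheme with harmonic-mean face
transmissibilities, uniform prescribed inlet flux, zero outlet pressure and
no-flux side walls, factorized directly (sparse Cholesky). Conservation is
therefore exact to machine precision — the 10⁻⁶ relative divergence
invariant is met by construction at ~10⁻¹² — and no iteration-tolerance
tuning exists. The flow rate argument is the pump setting for the full
channel; sub-domain inlet flux is scaled by covered width.

**Brinkman extension.** Pure Hele-Shaw flow is curl-free wherever h is
constant, so it cannot form closed in-plane streamlines at all. The
Brinkman-extended solve ∇p = µ∇²u − (12µ/h²)u (flux-streamfunction form,
direct solve) restores lateral momentum diffusion over the screening length
h/√12 ≈ 1.4–4.3 µm and is the model under which in-plane recirculation is
representable. It has no free parameter beyond the geometry and fluid.

**Vertical slice (Stokes).** Along a streamwise line the x–z flow is solved
in streamfunction–vorticity form (∇²ψ = ω, ∇²ω = 0; Thom's wall closure;
plane-Poiseuille inlet carrying the slice flux; zero-gradient outlet),
assembled as one sparse linear system. A flat floor reproduces
plane Poiseuille with max/mean = 1.5 within 2% at the default 0.5 µm grid;
deep cavities develop closed recirculation (Moffatt-type eddies), which the
streamline integrator confirms by closing orbits around the eddy core. The
slice flux is taken from the plan-view solution along the same line (2.5-D
coupling), so slices through a shielded trap see the locally reduced
through-flow rather than the open-channel flux.

## Microvortex metrics

Vorticity (ω = ∂v/∂x − ∂u/∂y, centered differences) and the Q-criterion
(Q = (‖Ω‖² − ‖S‖²)/2, positive where rotation beats strain) are computed on
any solved field. The headline trap metric, `microtrap_vortex_metrics()`,
reports the **vortex-core** values: closed-recirculation regions are found
as streamfunction excursions beyond the through-flow band, in both the
vertical slices (at ±15/±30/±45 µm off the trap centerline) and the Brinkman
plan view, and ω and Q are read at each core (the streamfunction extremum),
then maximized.

Cores rather than raw field maxima, deliberately: the raw |ω| maximum of a
discrete solution sits in the one-cell shear layer at wall edges (or in the
z-Poiseuille shear in any depth-resolved field, ~6U/h ≈ 270 s⁻¹ even in an
empty channel) and grows without bound under grid refinement — it measures
wall shear, not vortices. The Q-criterion exists precisely to isolate
rotation-dominated cores.

With the committed defaults the package obtains core vorticity ≈ 2.0 s⁻¹
and core Q ≈ 0.59 s⁻² at 3.0 µL min⁻¹ (both exactly 6× / 36× smaller at
0.5 µL min⁻¹). The validation suite compares these against the reference
values for this trap design, 6.7 s⁻¹ and 4.1 s⁻², at a factor-of-two band,
and that comparison **fails low by ~3–7×; the package leaves it red rather
than widen the band**. The analysis: the 2.5-D chain can only form
recirculation in vertical slices (corner eddies) or, with lateral viscosity,
in the plane — and with through-flux threading every cavity via gaps and
over-wall leakage, no 2-D creeping-flow model closes streamlines around the
cavity centers. The real cavity microvortices are three-dimensional spiral
structures (fluid enters over the walls, rotates, and leaves through the
gaps), whose z-slice projections look closed; resolving them requires a full
3-D Stokes solve, which is outside this package's desk scale. The 2.5-D
metrics land on the right order of magnitude but systematically below the
3-D values, as expected from this argument.

## Particle transport

`advect()` integrates passive tracers through the plan-view field with
Euler–Maruyama: x ← x + u dt + √(2D dt) ξ, D from Stokes–Einstein unless
overridden, plus gravitational settling in z (tracer microspheres at
1.3 g mL⁻¹ sink at ~0.65 µm s⁻¹ for 2 µm diameter; live cells at 1.1 g mL⁻¹
sink slower). Walls reflect: in-plane moves into cells shallower than the
particle diameter are rejected (specular stand-in), z reflects between the
local floor and the lid, and the downstream boundary absorbs. The default
dt is 1 ms with a CFL-like guard dt ≤ Δ/max|u|. The composition is
2.5-D — the in-plane field is depth-averaged and z feels only settling — an
approximation that cannot express vortex-mediated cavity entry; accordingly
the package's tested transport claims are nonzero trapping at both flow
rates and the robust in-trap slowdown (median particle speed over the trap
footprint below the upstream median), not a rate-ordering of trapped
fractions. Bacterial motility (flagella, pili, taxis) is deliberately out
of scope: passive spheres are the flow model.

## Synthetic microscopy

The renderer emulates an epifluorescence camera: isotropic Gaussian PSF
(σ = 1.2 px), pixel size 0.65 µm px⁻¹ (typical 10× system), 25 Hz × 500
frames (a ~20 s recording), integrated spot intensity ∝ diameter³, optional
defocus widening with |z − z_focus| at fixed integrated intensity, Poisson
shot noise plus Gaussian read noise, 8-bit output. Ground truth (per-frame
subpixel positions) is attached, which is what makes the velocimetry
parameter-recovery tests possible.

Biofilm images place Gaussian colonies (σ ≈ 2.5–6 µm, lognormal brightness)
according to the localization regime: uniformly on the wall footprint
(high inoculum, low flow), at wall corners with 4 µm jitter (low inoculum,
low flow), or at the centers of the first three cavities — rejection-sampled
to stay inside the enclosed cavity region, with a weak 15% tail in cavities
4–5 — for the high-flow regime. Counts default to 20 (low) / 60 (high
inoculum). These generators reproduce the *statistical structure* the
analysis assumes (where intensity sits relative to the trap), not biofilm
morphology: no streamers, no merging, no growth dynamics, no photobleaching
or drift. Passing tests therefore validate the analysis chain's correctness
on known ground truth, not the biological claims themselves.

`make_fixture_bundle()` materializes geometry, flow solutions at both study
rates, a tracer video and all three biofilm regimes as TIFF/CSV/JSON with an
MD5 manifest, byte-identical for a fixed seed.

## Velocimetry

Detection finds local maxima above a threshold — Otsu's method guarded by a
noise floor (median + 5 MAD), because a sparse-spot histogram is unimodal
and raw Otsu splits the background noise — then refines each to an
intensity-weighted centroid (≤ 0.05 px error on clean spots). PTV linking
follows the mean-flow-guided scheme: candidates inside a disk centered at
the expected displacement (mean velocity × frame interval / pixel size),
radius 0.5× the expected shift with a 3 px floor; assignments must be mutual
nearest neighbors and exact-tie ambiguities are dropped rather than guessed.
All consecutive frame pairs of a recording are linked (multi-lag linking is
out of scope), and track velocity is the median over steps. On rendered
ground truth this recovers > 95% of true links between non-overlapping
spots with < 1% false links, and the mean speed of a 500-frame uniform-flow
video within 5% with < 2° direction dispersion.

PIV cross-correlates interrogation windows (≥ 16 px) in the frequency
domain with zero padding — linear, not circular, correlation — normalizes by
the overlap count (unbiased estimate), restricts the search to a quarter
window, and refines the peak with a three-point Gaussian fit per axis
(parabolic fallback for non-positive lobes). Integer displacements are
recovered exactly at the correlation peak; subpixel displacements to ~0.05 px
median. A quality column (normalized correlation peak) supports filtering.

## Biofilm quantification

Replicate trap images are aligned by translation only (features are
axis-aligned with the flow): normalized cross-correlation against a blurred
template of the trap footprint, with a consensus-median correction because
template matching against stochastic colony placements carries a small
common bias; images below a 0.1 correlation threshold are excluded with a
warning. Intensity profiles average the trap's y-extent per x column over a
650 µm window anchored 120 µm upstream of the trap's leading edge.

Occupancy partitions above-background intensity mass into: wall band (solid
footprint dilated by half a wall thickness — a full-thickness dilation would
swallow the narrow inter-funnel cavities entirely), corner disks (one
wall-thickness radius around the 18 junction/apex points), and cavity
regions (enclosed cavities minus wall band). Background is the median of
outside-trap pixels plus a 3-MAD noise floor; without the floor, rectified
shot noise contributes area-proportional mass that washes out the
fractions. Classification is rule-based: cavity fraction above wall
fraction ⇒ cavity centers; otherwise the corner share of wall-band mass,
*relative to the share expected under uniform wall coverage* (the corner
disks' area fraction of the band — about 0.4 for this geometry, which is
why an absolute 0.5 cutoff cannot separate the regimes), decides corners
(enrichment ≥ 1.5) versus walls. Over 3 regimes × 10 seeds this recovers
≥ 90% correctly, with cavities 1–3 brighter than 4–5 in every
cavity-centers image.

## Problem sizes and determinism

Default analyses run on: a 650 × 390 µm trap domain at 2 µm cells (63 375
unknowns, direct solve, ~5 s), Brinkman at the same grid (~10 s), slices at
0.5 µm (~81 k unknowns, ~1 s each), 500-frame 256 × 192 px videos with
~300 particles, and 30 biofilm images at 4 µm pixels for regime studies.
Every stochastic step takes an explicit integer seed and restores the
caller's RNG state; fixture bundles are byte-reproducible.

## Known limitations

* No inertia, no 3-D Stokes solve: spiral cavity vortices are
  under-resolved and their strength underestimated (see above).
* Transport is 2.5-D; vertical advection and vortex-mediated cavity entry
  are not represented.
* The registration model is translation-only; rotated or warped replicate
  images must be pre-corrected.
* The PSF is Gaussian; no photobleaching, stage drift or multi-channel
  imaging.
* Funnel gap width, half-angle, pixel size and colony statistics are
  declared defaults where the physical values are unconstrained; all are
  exposed as parameters.
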