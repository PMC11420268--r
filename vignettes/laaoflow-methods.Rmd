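---
title: "Methods: modelling occluder position effects on appendage hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling occluder position effects on appendage hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After percutaneous left atrial appendage occlusion (LAAO), thrombus can form
on the atrial face of the implanted device (device-related thrombus, DRT).
Clinical series link DRT to *how* the device sits: deep implantation that
leaves part of the pulmonary-vein ridge uncovered, off-axis (tilted)
orientations, and device type (plug-style "non-pacifier" occluders vs
disc-style "pacifier" occluders). The mechanistic chain runs through local
hemodynamics: blood stasis, low wall shear permitting platelet adhesion, and
oscillatory shear activating the endothelium.

`laaoflow` builds a desk-scale in-silico version of this question: a
parametric left atrium with appendage, virtual implantation of both device
families in ostial, deep, tilted and proximal positions, pulsatile laminar
flow under atrial-fibrillation (AF) inflow, and the standard surrogate
markers of thrombogenicity. The aim is *trend-level* reproduction of the
position and device effects, not patient-specific prediction.

## Surrogate markers

For a region of interest (ROI) in front of the device's atrial face — a
40 mm sphere centred on the appendage ostium midpoint, excluding the
appendage distal to the device — the package computes:

* volume-averaged speed and vorticity over the last cardiac cycle;
* residual blood fraction $\varphi = V_\text{old}/V_\text{ROI}$: a passive
  tracer is set to 1 everywhere at the start of the evaluation window and
  enters as 0 through the pulmonary veins; $\varphi$ is its
  concentration-weighted volume fraction in the ROI;
* washout half-time $t_h$: first crossing of $\varphi = 0.5$, linearly
  interpolated, censored if not reached;
* per-face wall shear stress $\tau_w = \mu\,(\partial u/\partial y)_{y=0}$
  on tissue and device surfaces in the ROI, integrated over the last cycle:
  $\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\tau_w|\,dt$, the oscillatory shear
  index $\mathrm{OSI} = \frac12\left(1 -
  \frac{|\int_0^T \tau_w\,dt|}{\int_0^T |\tau_w|\,dt}\right) \in [0, 0.5]$,
  and the endothelial cell activation potential
  $\mathrm{ECAP} = \mathrm{OSI}/\mathrm{TAWSS}$;
* threshold-exceedance area fractions: TAWSS below the 0.36 Pa
  platelet-adhesion threshold, ECAP above the 1.4 Pa⁻¹ activation
  threshold.

A residual fraction can also be computed with a binary 0.5 cut
(`threshold =` in `residual_fraction()`), which mimics red iso-volume
renderings; the concentration-weighted form is the default because it needs
no arbitrary cut.

## Synthetic anatomy

No patient geometry is distributed. The generator (`laa_anatomy()`)
composes an implicit solid: an ellipsoidal atrial body (default semi-axes
30 × 26 × 24 mm, volume ≈ 78 mL), four pulmonary-vein inlet tubes (radius
6 mm, length 30 mm), a mitral outlet tube, and a tapered conical appendage
with a rounded apex. Signed distances are unioned and voxelized on a
uniform Cartesian grid; boundary faces are classified into wall, the four
PV inlet caps and the mitral outlet. Diagonal "pinch" configurations are
repaired so the extracted surface is edge-manifold (every edge shared by
exactly two faces). An STL import path (`voxelize_stl()`) can replace the
generator.

Defaults were chosen once, from device-sizing constraints rather than any
patient: the ostium diameter is 24 mm and the taper 0.675 so that a plug
occluder deployed at 24 mm meets its landing zone at ~11 % compression,
inside the 8–20 % release criterion. The mitral outlet is modelled with a
12.5 mm radius and a 10 mm tube length — i.e. the "10 mm outlet tube" is
read as a tube *length* on a normal ~25 mm mitral annulus, the only reading
consistent with laminar outlet flow (peak Reynolds number below 2300) at
physiological flow rates. The appendage is a single tapered cone; real
appendages have wide landing zones and lobes, so *deep* placements in this
geometry over-compress (the release-criterion warning fires for the deep
and disc scenarios) — the warning is informational and the flow study is
unaffected, but compression rates for deep placements should not be read
as device-sizing guidance.

The 1 mm tissue wall thickness that a structural model would need is not
represented; only the blood pool is meshed, and walls are rigid.

## Devices and virtual implantation

Two families are modelled for the fluid domain only (`laao_device()`):

* **plug (non-pacifier)**: a capped cylinder seated inside the appendage;
  deployed diameters 24 mm (size 27) and 21.6 mm (size 24); atrial face
  with a rounded shoulder (2 mm) and a central cylindrical cove — the
  threaded-insert recess (radius 3.5 mm, depth 2.5 mm), a clinically
  reported DRT niche;
* **disc (pacifier)**: a 4 mm-thick disc covering the ostium (disc
  diameters 32 mm for size 25, 28 mm for size 22) with a central insert
  protruding 2.5 mm into the atrium. The distal lobe is omitted: it is
  sealed off from the blood pool and does not affect the hemodynamics.

Cove, shoulder and insert dimensions are documented model constants, not
manufacturer data. Deployment (`deploy()`) is a geometric union with
bounded wall accommodation: grid cells inside the expanded device become
device cells even where the tissue stood, emulating penalty-free radial
dilation up to the deployed diameter. This replaces a finite-element
collapse/expand simulation; the flow study needs the post-deployment lumen
shape, not the tissue stress state. Fluid pockets sealed off from the
outlet (the appendage behind a well-seated device) are removed by flood
fill, which doubles as the seal check: a placement is *sealed* when no
fluid cell distal to the device survives.

Position metrics (`measure_position()`) are taken in the plane containing
the appendage axis and the pulmonary-vein ridge anchor (the analogue of the
lower-middle transesophageal view with 90° rotation): the uncovered ridge
length (wall arc from the limbus to the device's atrial rim; deep
implantation means > 10 mm), the matching depth on the mitral side
("implant depth towards the MV" is referenced to the ostium plane, since no
annulus landmark exists in the parametric anatomy), and the device–ridge
angle α (180° minus the in-plane tilt). Deep placements are specified by
their target ridge length and inverted analytically
(`depth_for_ridge()`).

The nine-scenario suite (`scenario_suite()`) comprises the pre-occlusion
model; the plug in clinically-typical slightly-proximal, ostium-fitted,
tilted (α = 166.4°, with a 4 mm lateral offset that leaves a peri-device
gap) and deep (ridge 27 mm, smaller plug) positions; and the large/small
disc in ostial and deep (ridge 10.1 / 15.5 mm) positions. The deliberate
peri-device gap of the tilted plug is what lets flow and fresh blood enter
the appendage in that scenario only.

## Flow model

Blood is Newtonian and incompressible (ρ = 1060 kg/m³, μ = 0.0035 Pa·s);
flow is laminar; walls (tissue and device) are rigid and no-slip. The four
pulmonary veins carry a transient AF velocity inflow; the mitral outlet is
a zero-gauge pressure outlet; there is no mitral valve motion.

The AF waveform (`af_waveform()`) is two raised-cosine pulses per 1.01 s
cycle — a systolic S wave and a diastolic D wave — on a small baseline,
with no atrial-contraction wave. The published echocardiographic traces it
emulates are not reproduced numerically; instead the amplitudes (S 0.36,
D 0.45, baseline 0.09 m/s) were calibrated once so that the pre-occlusion
ROI mean velocity lands in the reported 0.04–0.07 m/s range, and then
frozen. At these amplitudes the peak Reynolds number over tubes and ostium
stays below 2300 (≈ 1900–2100), consistent with a laminar model.

### Discretization

The solver is a fractional-step (projection) method on the voxel grid:
explicit first-order upwind advection and explicit central diffusion on
cell-centred velocities, then a pressure Poisson solve that zeroes the
divergence of the *face* volume fluxes exactly (to sparse-Cholesky
round-off). Boundary conditions: inlet faces carry the waveform velocity
along the tube axis, scaled by the staircase projection factor so each
vein carries the nominal volume flux; the outlet is Dirichlet zero
pressure with zero-gradient velocity (backflow is clipped to zero normal
derivative); walls use ghost-cell no-slip; symmetry (free-slip) faces are
available for the channel benchmarks. The Poisson matrix is factorized
once per scenario (sparse Cholesky from the `Matrix` package) and reused
every step. Steps exceeding an advective CFL of 0.7 — or the explicit
diffusion limit — are sub-stepped. Everything is deterministic: fixed cell
ordering, no random numbers, so identical configurations give bit-identical
results.

The full protocol is a fixed 5 ms time step, 10 warm-up cycles and 6
evaluation cycles (2020 + 1212 steps). Resolution tiers scale this to desk
size: the `test` tier runs 2 + 2 cycles at h = 2.5 mm (≈ 6,700 fluid cells,
the whole 9-scenario suite in a few minutes on one CPU), `standard` 4 + 4 at
2.0 mm, `fine` the full 10 + 6 at 1.6 mm. All of these are far below the
~500k-cell meshes of full-scale studies — the package's results are
trend-level by construction, which is why the acceptance checks assert
orderings and signs, not absolute marker values.

Wall shear uses the one-sided gradient: the tangential velocity of the
first fluid cell divided by the half-cell wall distance. On the Poiseuille
benchmark this estimator is the dominant error term (h/4a relative), which
sets the benchmark resolution.

### Validation

Three closed-form benchmarks exercise the full stack
(`benchmark_poiseuille()`, `benchmark_womersley()`, `benchmark_washout()`):
plane Poiseuille wall shear (τ = 2μu_max/a, error ≈ 1 % at 16 cells across
the gap), oscillatory Womersley channel flow at α ≈ 6.9 (relative L2
velocity error ≈ 2 % over a cycle), and the single well-mixed compartment
washout (t½ = ln 2 · V/Q, error ≈ 1 %). Mass balance holds to solver
round-off every step; a closed box conserves tracer to 10⁻¹².

## Tracer transport

The "old blood" tracer advects conservatively on the projected
(divergence-free) face fluxes with a minmod-limited second-order upwind
scheme, sub-stepped to CFL ≤ 0.45, so it is monotone and conserves mass to
round-off. There is no molecular diffusion term; numerical diffusion is
bounded by the limiter and shrinks at least linearly under refinement (the
translation test error at least halves at 2× resolution). The tracer is
initialized to 1 at the start of the evaluation window — "old blood with
respect to the first evaluated cycle" — and the whole-domain residual
fraction is provably non-increasing (inlets inject zero concentration).

## Numerical and design choices

* **Collocated velocities with face-flux projection** rather than a fully
  staggered arrangement: the divergence constraint, mass balance and
  conservative tracer transport all live on the face fluxes and are exact;
  the cell-centred field sees an approximate projection. This keeps the
  masked-domain bookkeeping simple at identical conservation guarantees.
* **Integration period** for TAWSS/OSI/ECAP is the last evaluation cycle;
  the stored series allow integrating over all cycles instead.
* **Vorticity conventions**: the ROI vorticity is reported both
  volume-averaged (1/s) and volume-integrated (m³/s), because both
  conventions appear in summaries of this kind; they differ by the ROI
  volume factor.
* **ECAP exclusions**: faces with zero TAWSS (no shear all cycle) are
  excluded from area averages and flagged; OSI on zero-shear faces is 0.
* **Degenerate inputs**: empty ROIs, unresolved tube caps (< 3 cells
  across), self-intersecting tube layouts, and single-sample marker
  integrations raise typed errors naming the offending part.
* **Half-time censoring**: with 2 evaluation cycles several scenarios do
  not reach φ = 0.5 inside the window; the half-time is censored rather
  than extrapolated, and the final φ carries the comparison.

## What passing the tests shows — and what it does not

The synthetic generator emulates the *topology* and scale of a real left
atrium (chamber, four veins, outlet, ridge, tapered appendage) and the
deployed geometry of both device families, so position- and device-driven
differences in stasis and shear have the same causal pathway as in
patient-specific studies: a deep plug leaves a cul-de-sac; a tilted plug
leaves a gap and a stagnation pocket; a disc presents a smooth, proud face
to the atrial sweep. The suite reproduces the qualitative ordering (deep:
more residual blood, lower WSS, higher ECAP; tilted: more residual blood,
higher ECAP; disc vs plug: less residual blood, higher WSS, lower ECAP;
only the tilted plug admits flow into the appendage).

It does not show: absolute marker values at clinical resolution (our cells
are ~15× coarser by linear dimension than full-scale studies, so WSS is
systematically underestimated and ECAP overestimated); effects of wall
motion, mitral valve dynamics, non-Newtonian rheology, or anatomic
variability (one parametric anatomy, as one patient anatomy in the original
setting); and any non-hemodynamic contributor to DRT.
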