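---
title: "Measurement-integrated carotid flow simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-integrated carotid flow simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umiflow)
```

## What the package computes

umiflow couples three things that are usually studied separately:

1. a **2D unsteady blood-flow field** in a carotid-like vessel, computed by a
   finite-volume Navier–Stokes solver whose solution is continuously nudged
   toward color-Doppler velocity measurements (an *ultrasonic-measurement-
   integrated*, or UMI, simulation — a flow observer in control-theory terms);
2. a **blood-pressure pulse waveform** obtained from photoplethysmography
   (PPG), calibrated by cuff systolic/diastolic values and synchronized to the
   ultrasound clock through an image-derived pulse;
3. **wave-intensity analysis** — WI(t) = dP/dt · dU/dt — and the PU loop,
   which classify each instant of the cycle as forward-wave dominated
   (positive WI), backward-wave dominated (negative WI) or absorption-type
   (positive WI with falling pressure and velocity), and diagnose residual
   clock misalignment from the curvature of the systolic PU limb.

Because clinical recordings of this kind are not redistributable, the package
ships a **synthetic twin-experiment generator**: a known "truth" flow drives
simulated Doppler frames, B-mode-like image stacks, Beer–Lambert PPG and a
synthetic ECG, so every stage of the chain can be validated against a ground
truth that is known by construction.

## Flow model

The blood is treated as incompressible and Newtonian (density
ρ = 1.0×10³ kg/m³, viscosity μ = 4.0×10⁻³ Pa·s) in a rigid 2D channel whose
axis is aligned with x; three-dimensionality and wall motion are deliberately
ignored. The governing equations are the 2D Navier–Stokes equations with an
artificial body force **f**, plus the pressure equation derived from
continuity:

- momentum: ρ(∂**u**/∂t + **u**·∇**u**) = −∇p + μ∇²**u** + **f**
- continuity: ∇·**u** = 0

The feedback force on the measurement points is

  **f** = −K\*ᵥ (ρU/L) (V_c − V_m) **ê**,

where **ê** is the ultrasound beam unit vector, V_c = **u**·**ê** the computed
and V_m the measured Doppler velocity, and U, L characteristic scales
(defaults 0.1 m/s and the 6.4 mm upstream diameter). The sign drives V_c
toward V_m; with the default non-dimensional gain K\*ᵥ = 500 the feedback term
dominates the local momentum balance by two orders of magnitude, which is
what makes the observer converge — and what makes naive explicit treatment
unstable. The solver therefore linearises the force about the current iterate
and carries its diagonal part (−K\*ᵥρU/L · êᵢ² per velocity component) on the
matrix diagonal; the force value at convergence is unchanged.

### Discretisation

- Orthogonal, equidistant, **staggered** grid: pressure at cell centres,
  velocity components on faces. The default spacing equals the Doppler
  measurement resolution (Δx = 163 μm, Δy = 173 μm on a 36 × 86 grid).
- Walls are **stair-step** (no cut cells). The near-wall diffusive flux and
  the wall-shear extraction both use a one-sided quadratic fit through the
  first two interior samples, which is exact for a parabolic profile; steady
  plane Poiseuille is reproduced to the solver tolerance (the package's
  analytic acceptance test asks for 2%, and the discrete solution is
  essentially exact).
- Convection: **QUICK** by deferred correction — first-order upwind carried
  implicitly, the quadratic upstream-biased correction explicitly; near
  boundaries where the second upstream node does not exist the scheme falls
  back to upwind.
- Time: second-order implicit **BDF2** (backward Euler for the first step).
  Halving dt reduces the error on a smooth pulsatile solution by ~4×, which
  the test suite checks. The default dt = 29.075 ms is one Doppler frame at
  34.394 Hz.
- Pressure–velocity coupling: **SIMPLER-style** — a pressure equation built
  from the momentum pseudo-velocities (the body force thus enters its source
  term), momentum solves, then a pressure-correction step that restores
  discrete continuity. Sparse LU (Matrix package) solves each linear system;
  the original pentadiagonal MSI iteration is an implementation detail of the
  reference hardware era and any robust sparse solver satisfies the same
  converged-field contract.
- Boundary conditions: parabolic (or user-shaped) inlet profile renormalised
  to a prescribed discrete mean; no-slip walls; zero-streamwise-gradient
  outlet with an additive global mass correction, so inlet and outlet fluxes
  agree to round-off at every converged step. Under transient outlet inflow
  the outlet convective flux is split implicit/deferred to keep the diagonal
  positive; the converged solution is unchanged.
- Outer iterations stop when non-dimensional mass and momentum residuals
  fall below 10⁻² (the reference criterion). The mass residual is the summed
  cell imbalance scaled by the inlet mass flux ρ·U_ref·h; the momentum
  residual is the summed equation imbalance scaled by the total momentum
  content Σ|a_P·u| — the scaled-residual convention of finite-volume
  practice. U_ref is the larger of the inlet mean and the current field
  maximum (floor 0.01 m/s, so a zero-flow state converges immediately).
  Steady solves and accuracy-critical tests use tighter tolerances
  (10⁻⁴–10⁻⁶), since 10⁻² is a per-time-step criterion for warm-started
  transient iterations, not a steady-state one. Under-relaxation defaults:
  momentum 0.7, pressure update 0.3.

### Inlet estimation

The mean inlet velocity of each frame is found by **golden-section search**
on the Doppler error norm

  e(t) = (1/N_e) Σ |V_c − V_m| / V_type,  V_type = 0.39 m/s,

summed over valid measurement points inside the feedback domain (x from 1/36
to 29/36 of the domain). Each candidate runs one fully converged implicit
step — not a surrogate — warm-started from the previous candidate's field.
The search is pure golden section (not Brent), matching the named method; it
terminates when the bracket is narrower than 10⁻³·U (10⁻⁴ m/s). The first
frame searches the full [−0.2, 1.5] m/s bracket; subsequent frames use a
0.4 m/s window re-centred on the previous frame's estimate, generous
against the ~0.1 m/s frame-to-frame excursion of a carotid waveform sampled
at 34 Hz. The
initial condition of a run is a steady solve at a least-squares projection
guess from the first frame; e(U) is assumed unimodal on the bracket, which
holds for the channel flows treated here because V_c responds monotonically
to the inlet mean.

An *ordinary* (2D-O) simulation is the identical loop with K\*ᵥ = 0 — the
inlet is still estimated, but nothing corrects the interior field. On a
noiseless twin whose true inlet profile is skewed (η(1−η)², peaked toward
one wall) while the simulation imposes a parabola, the ordinary run keeps a
persistent interior error while the UMI run removes most of it: the bundled
acceptance test requires the time-averaged e(t) ratio to be ≤ 0.5 and the
UMI error to be below the ordinary error at every frame after the third; in
practice the ratio on this twin is ≈ 0.2.

## Signal chain

- **ECG**: notch (50 Hz, 10 Hz bandwidth, −90 dB), high-pass (FIR order 250,
  stop 2 Hz / pass 5 Hz) and low-pass (FIR order 200, pass 20 Hz / stop
  30 Hz) at 200 Hz. All stages are linear-phase Kaiser-window FIR designs
  (the band specification fixes everything except the window; the notch
  order, 400, is chosen so the −90 dB target is met with margin), applied
  with exact group-delay compensation and reflection padding, so filtering
  is linear and delay-free. R peaks are per-cycle maxima with a refractory
  separation; ties keep the earlier sample.
- **PPG**: Beer–Lambert, I = |I₀|e^(−ε(λ)Cℓ), λ = 940 nm; the haemoglobin
  concentration C is constant for vessels of this calibre, so intensity
  follows the optical path ℓ(t) and hence lumen size, anti-phase. The pulse
  is normalised to [0, 1] per record and calibrated affinely so its extrema
  match the cuff systolic/diastolic pressures, giving P₀(t) in mmHg.
- **Image pulse**: each B-mode-like frame is binarised with Otsu's threshold
  (lumen darker than tissue), split by a watershed on the distance map, and
  the largest lumen object's pixel count forms the 34.394 Hz area waveform;
  it is least-squares scaled (a·x + b) onto the normalised PPG.
- **Clock synchronization** is two-stage. Coarse: the integer-millisecond
  shift minimising the mean squared difference of per-cycle peak times over
  six cardiac cycles (search ±500 ms; nearest-neighbour pairing; ambiguous
  pairings discarded; ties prefer the smaller |shift|). Peak times are
  refined by a 3-point parabolic fit around the sampled maximum — at 34.4 Hz
  the raw argmax would quantise peaks to ±14.5 ms, defeating 1-ms alignment.
  Fine: the velocity channel is shifted in 5-ms steps over ±30 ms and the
  shift maximising the systolic PU-loop R² is kept. On twins with ±300 ms
  offsets and 5 ms peak jitter the combined recovery error is ≤ 10 ms in
  well over 90% of trials (the refinement step bounds the residual by half
  its 5-ms quantum plus the jitter-limited coarse error).

## Wave analysis

Derivatives use a 5-point local quadratic (Savitzky–Golay) at 200 Hz; the
34.4 Hz inflow series is linearly interpolated to 200 Hz first. WI is
computed with pressure converted to Pa. Labels: *forward* (both derivatives
positive, WI above threshold), *backward* (WI below −threshold), *absorption*
(both derivatives negative, WI above threshold — the late-cycle forward
wave that stops the flow); the significance threshold is 5% of the record's
peak |WI|, a stand-in for the visual peak-picking a human analyst does. Both
absorption-type peaks, when present, are reported ordered by time with no
clinical interpretation attached.

The PU loop plots P (vertical) against U (horizontal); its systolic window
runs from the intersecting-tangents foot of the U upstroke to the U peak.
Straightness is the R² of a linear fit; curvature is the sign of the
quadratic coefficient of a parabola fitted on range-normalised axes, with
|coef| ≤ 0.05 declared straight. The geometric sign convention — delayed
pressure → loop below its chord → *concave*; advanced pressure → *convex* —
is fixed by regression tests on synthetic shifted water-hammer pairs rather
than by intuition, since it depends on axis orientation.

## The twin generator and what it does not emulate

The default scenario mirrors the reference acquisition: straight 6.4 mm
channel inside an 86-cell-deep raster, 36 axial columns, frame rate
34.394 Hz, beam 20° from the depth axis, inlet mean 0.3 m/s with three
harmonics spanning ≈ 0.1–0.5 m/s over a 0.9 s cycle, K\*ᵥ = 500,
V_type = 0.39 m/s. Doppler noise is i.i.d. Gaussian per point — real speckle
is spatially correlated and the instrument-specific measurement-error
compensation of the original system is not reproduced, so noisy-twin
behaviour is tested empirically rather than guaranteed. B-mode frames are
ellipses with multiplicative log-normal speckle, not physical ultrasound
point-spread functions; the ECG template is only R-peak faithful. Passing
twin tests therefore demonstrates correctness of the algorithms under known
conditions, not robustness to every clinical artefact.

Problem sizes in the bundled tests are chosen to keep a full run on one CPU
comfortable: the assimilation twins use the full 36 × 86 grid with 35 frames
(the gain-sweep reuses the first 12), solver unit tests use a 12 × 16
channel, and the synchronization study uses 100 seeded trials; all
generators are bit-reproducible under a fixed seed.

## Numerical choices and edge cases

- Lumens must be 4-connected, span the full axial extent, and be at least 3
  cells thick everywhere; column cross-sections must be contiguous.
- Principal-axis rotation uses image second moments in physical units;
  eccentricity below 0.9 means "no dominant axis" and is rejected.
- The golden-section objective evaluates a fully converged step per
  candidate; non-convergence raises with the residual history attached.
- The pressure equation is pinned at one reference cell (pressure is
  relative); the outlet mass correction is additive and re-applied after the
  correction step.
- A flat ECG yields an empty timing table with a warning; frames without a
  detectable lumen are interpolated with a warning; a beat without an
  upstroke yields a missing PTT.
- Serialization uses plain-text containers (annotated CSV for signals,
  CSV + JSON for Doppler stacks, JSON for grids) and multi-page TIFF for
  image stacks; all physical quantities are SI internally, with mmHg only at
  the calibrated-pressure interface and unit-suffixed keys in the YAML
  config.

## Known limitations

Rigid walls and 2D flow are assumptions inherited from the modelled system;
pulse-wave velocity and augmentation index are out of scope. The
pressure–area relation underlying both PPG calibration and the image pulse
is linearised between the cuff extremes; whether lumen change tracks
pressure faithfully is an open question of the underlying methodology, not
resolved here. The feedback acts only on the beam-projected velocity
component inside the feedback domain, so cross-beam velocity errors are
corrected only indirectly through the momentum coupling.
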