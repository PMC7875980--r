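---
title: "Models and algorithms behind autopatchr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms behind autopatchr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autopatchr)
```

# Scope

`autopatchr` implements the computational core of a label-free, image-guided
automated patch-clamp workflow: locating the pipette tip in a DIC-like
z-stack, calibrating pipette-to-stage motion, detecting and ranking cell
somata in 3D, tracking the target cell while the pipette approaches it, and
driving the full patching protocol (hunt, descend, seal, break-in, clean,
harvest) as a finite-state machine. Because the package targets algorithm
development rather than a specific rig, every hardware-facing element is
replaced by a simulated counterpart: image phantoms with exact ground truth
and an electrophysiology rig model with first-order pressure dynamics, a
seal-growth law and a membrane-rupture rule. All randomness is seeded, so
every figure and number below is reproducible bit-for-bit.

This vignette explains the models, their parameters and units, the numerical
choices, and what the synthetic test bed does and does not establish about
behaviour on real tissue.

# The synthetic test bed

## Image phantoms

`generate_cell_phantom_stack()` emulates an unstained neocortical slice
viewed with a 40x DIC objective:

* **Background**: mid-grey (0.5) plus a smoothed-noise texture (Gaussian
  scale 8 px, amplitude 0.03 intensity units). The texture decorrelates
  along z as an AR(1) process (coefficient 0.85 per 1 µm slice), emulating
  tissue clutter moving through focus; it is generated on a padded field
  and cropped so blur boundary effects never reach the image.
* **Somata**: elliptical Gaussian blobs with radii drawn from 4–7 µm,
  aspect ratio 0.8–1.25, contrast 0.25 above background. A soma is
  brightest and sharpest at its centre slice; away from it the amplitude
  decays as a Gaussian of z-distance (σ = 3 µm) and the lateral footprint
  widens by `sqrt(1 + (dz/3)^2)`, so an annotation around the centre slice
  remains recognisable for roughly five slices — the convention the
  annotation-expansion helper reproduces.
* **Placement**: rejection sampling with pairwise centroid distance above
  twice the maximal radius plus 1 µm, and an XY border margin; impossible
  densities raise an error rather than degrade.

`generate_pipette_phantom()` renders the pipette silhouette into the same
background (texture amplitude 0.03 at blur scale 12 px): two Gaussian wall
tubes (scale 0.7–0.9 µm) diverging from the tip by a half-opening of
0.25–0.35 rad, darkened multiplicatively with contrast 0.7 — pipette glass
in DIC is nearly black. Tip position and orientation are drawn uniformly
(tip in the central third of the volume; yaw free; tilt 33° ± 8° above the
horizontal, the usual mounting angle). Optional voxel noise is expressed as
a fraction of the stack's dynamic range.

The camera-facing renderer (`render_cell_frame()`) additionally gives each
soma a fixed speckle texture that moves rigidly with the cell, so that the
feature tracker has corners to lock onto, as real somata do.

What the phantoms deliberately omit: DIC shear/relief shading, depth-
dependent light scattering, deformation of tissue by the advancing pipette,
and non-rigid cell shape change. Consequences are discussed at the end.

## The simulated rig

`rig_create()` bundles the hidden truth the controller must cope with:

* **Calibration**: a 3×3 matrix mapping pipette-axis displacements to stage
  displacements. The default advance axis is tilted −33° from the
  horizontal (advancing descends); no orthogonality is assumed anywhere.
* **Pressure**: first-order relaxation toward the setpoint with
  τ = 0.2 s.
* **Resistance**: baseline pipette resistance drawn once from 3.5–5 MΩ.
  Obstacles add their bump while the tip is inside their radius. A cell
  within contact distance (radius + 1 µm) adds a 1.0 MΩ contact jump — the
  centre of the 0.7–1.2 MΩ detection window. A −5 mV test step obeys
  Ohm's law (1 nA through 5 MΩ).
* **Seal growth**: in cell-attached contact under suction,
  `dR/dt = k(p) (Rmax − R)` with `Rmax = 2000 MΩ` and
  `k(p) = 0.05 /s × min(|p|, 30)/20` for negative pressures, scaled by a
  per-cell rate factor (0.8–1.2). A default sealable cell crosses 1 GΩ at
  −20 mbar in about 14 s, inside the 10–25 s window chosen as realistic;
  non-sealable cells have zero growth. Once a seal exists the cell is
  anchored to the glass: it stops drifting and remains in contact.
* **Break-in**: once gigasealed, suction at or below −100 mbar accumulates
  impulse `|p|·dt` (mbar·s); crossing the cell's rupture threshold
  (default 250 mbar·s, reached on pulse 3–4 of the standard pulse train
  given the pressure lag) ruptures the patch deterministically, and the
  measured resistance drops to baseline plus the cell's access resistance,
  drawn log-normally with median 30 MΩ. A deterministic threshold was
  preferred over a stochastic rupture model to keep every controller test
  exactly reproducible.

The seal and rupture constants are internal free parameters of the test
bed: they were fixed once, from plausibility arguments, and all controller
timing tests inherit them.

# Pipette tip localization

## Darkness map

The pipette manifests as the darkest structure in the stack. Each slice is
inverted about its median (making the map invariant to constant intensity
offsets), clipped at zero, smoothed (Gaussian σ = 1.5 px), and the stack is
normalized by its 99.95th percentile through `tanh`. The soft saturation
matters: a hard clip at 1 flattens the map over the wall core and with it
the fitting energy, which then loses its gradient exactly where precision
is decided.

## Two-cylinder model and energy

The pipette model has seven parameters: tip (x, y, z in stage µm), yaw,
tilt, wall half-opening angle, and wall tube scale. The fitting energy is
the negative mean darkness over stratified samples (500 per wall) along the
two wall axes from the tip to where each axis leaves the volume; at the
true pose the samples ride the dark wall cores and the energy approaches
−1.

## Initialization

Initialization works on the 3D cloud of near-saturated map voxels
(value ≥ 0.65), which on a pipette stack is essentially the wall cores.
Its darkness-weighted principal axis approximates the wall bisector; the
axis is oriented by regressing the cloud's cross-sectional width on the
axial coordinate (the silhouette converges at the tip), and the tip is the
weighted centroid of the extreme 0.5 % of the cloud at the narrow end.
Because a wall that leaves the volume biases both the axis and the end
decision, the initializer emits a fan of candidate poses — both ends,
the estimated and the nominal 33° tilt, and yaw offsets up to ±24° — and
screens them by the fitting energy. Degenerate inputs fail loudly: a blank
or noise-only stack has either no dark voxels, a mask covering most of the
image, or an isotropic cloud, each of which raises a detection-failure
error.

## Refinement

`refine_pipette_model()` is a scaled gradient descent: central-difference
gradients (step 0.05 of each parameter scale — 1 µm for positions, 0.02 rad
for angles, 0.2 µm for the wall scale), a backtracking line search
(shrink 0.5), acceptance only on strict decrease (so the energy trace is
non-increasing by construction), and stop at an accepted improvement below
1e−6 or 500 iterations. Descent alone converges poorly along one specific
valley — sliding the tip along the pipette axis changes the energy only
through the slow divergence of the walls — so a derivative-free simplex
polish runs afterwards and is kept only when it improves the energy.
`detect_tip()` briefly refines the best few initialization candidates
(40 descent iterations, 300 samples, no polish) and refines the winning
basin to convergence; this multi-start costs seconds and removes the rare
tip/body confusions on truncated silhouettes.

On the standard phantom geometry (80 slices × 288 × 288 px at 0.115 µm/px,
the published field-of-view calibration) the full detector localizes the
tip to a mean error near 0.14 µm over 20 seeded stacks with noise up to 5 %
of the dynamic range — comfortably under the ~1 µm regime needed to hit a
10 µm soma. One caveat worth recording: on rare geometries the global
energy minimum itself sits a few tenths of a micrometre from the true tip
(the displaced optimum is *lower* in energy than the refined true pose), so
sub-0.1 µm accuracy is not guaranteed per stack, and the package's accuracy
claims are stated as means over a seeded suite
(`pipette_localization_suite()`).

## Calibration

`estimate_calibration()` solves `observed = A · delta` by least squares
over at least three linearly independent moves; it is exact on noiseless
data for any invertible `A` and recovers the default tilted matrix to
within 2 % per entry from six 50 µm moves with 0.5 µm observation noise.
The inverse map (`stage_to_pipette()`) is what the trajectory planner uses
to express stage-space goals in manipulator coordinates.

# Cell detection in 3D

The per-slice detector is deliberately classical — difference-of-Gaussians
matched to the expected soma radius, local maxima above
`max(0.02, 3.5 × MAD)` of the bandpass response, confidence equal to the
response normalized to the strongest blob in the image, and a
response-weighted centroid refinement. It is the reference detector for
phantoms and the contract for plugging in a trained network: any callable
`image → (x, y, w, h, confidence)` works.

Z-merging follows the intersection-region rule: boxes are processed in
ascending slice order (canonically sorted within a slice, which makes the
result invariant to input permutation); a box joins an open detection when
its slice lies 1–3 above the detection's last member slice (so up to two
empty slices may intervene, compensating missed detections) and its
intersection with the detection's *running intersection region* is at least
60 % of the smaller area. On joining, the running region shrinks to the
intersection unless that would fall below 4 px², a floor that prevents the
region from vanishing on long cells. Every input box lands in exactly one
detection. The 3D confidence is the maximum over members; the centroid is
the confidence-weighted mean of member box centres — both conventions are
package choices where the field has none, and the ranking used to offer
cells is descending confidence with a deterministic spatial tie-break.

Evaluation uses centroid distances with two separate tolerances: 5 µm
lateral (Euclidean in XY) and 3 µm axial. Matching is greedy by ascending
lateral distance and one-to-one; greedy equals the optimal assignment
whenever ground-truth tolerance neighbourhoods are disjoint, and the test
suite verifies this equivalence against an exhaustive-assignment oracle on
instances of up to six objects. Precision, recall and F1 follow the
standard formulas with zero-denominator conventions, reported as
percentages.

# Tracking

Lateral tracking is pyramidal Lucas–Kanade over minimum-eigenvalue
(Shi–Tomasi) corners inside the target box: at most 30 features, 3 pyramid
levels, 15 px windows, bilinear sub-pixel sampling; the reported
displacement is the median over surviving features after a 1 px inlier
gate, and features are re-selected when more than half are lost. On
speckled phantom cells it recovers translations up to 10 px to better than
0.2 px noiseless and 0.5 px under 2 % noise. No optical-flow implementation
exists in the installed R stack, so the tracker core is implemented here.

Axial tracking compares each slice of a small stack (half-depth 3, odd
count enforced) against the pre-patch template over the target box using
the standard deviation of the difference image; the minimum marks the
cell's focal plane. Sign convention (documented in the configuration):
+z is up, i.e. increasing slice index, and a mini-stack centred 2 µm above
the true focus therefore reports a drift of −2 µm. Tracking queries run
only while the pipette is halted; the accumulated offset corrects the
planner's target.

# The autopatching state machine

Phases run HUNT → DESCEND → SEAL → BREAKIN → WHOLE_CELL with failure edges
only, and HUNT is re-entered solely after obstacle avoidance. The
simulation clock is discrete-event with dt = 50 ms; all protocol durations
are quantized to it.

* **Planning**: a single lateral pre-positioning move, then 2 µm steps
  along the manipulator X axis to a staging point 5 µm above the target,
  then a pure stage-Z descent. Targets beyond the manipulator's travel
  fail before any motion.
* **Hunting** at 60 mbar (50–70 allowed): after each step the test-pulse
  resistance is compared with the running baseline (mean of the last five
  clear reads). A jump at more than 10 µm lateral distance from the target
  is an obstacle; within 10 µm it is treated as early cell contact — the
  published criterion is only that obstacle hits are "early", so the
  10 µm disambiguation radius is a package choice.
* **Obstacle avoidance**: pull back 6 µm, probe lateral offsets on an
  Archimedean spiral (pitch 1 µm, 8 points per turn, 15 µm maximum
  radius), advance past the obstacle at the first clear offset, return to
  the trajectory, re-track and re-plan. The numbered sub-steps are logged
  in order; an exhausted spiral ends the attempt as `OBSTACLE_FAIL`.
* **Descent** at 20 mbar (10–30): 2 µm Z steps; contact is a resistance
  rise of at least 1.0 MΩ over baseline. Descending more than twice the
  staging offset plus one expected cell diameter without contact is a
  missed-cell error.
* **Sealing**: pressure ceases immediately at contact, then −20 mbar
  suction while the holding potential ramps in −10 mV steps per second to
  −60 mV. If 1 GΩ is not reached in 30 s, escalation runs strictly in
  order: suction ×1.5 for 20 s, ×2 for 20 s, a ±2 µm wiggle on each axis
  (2 s per axis), pressure release for 10 s, reapplication for 20 s;
  exhaustion is `SEAL_FAIL`. Seal-phase setpoints therefore never leave
  [−60, 0] mbar.
* **Break-in**: suction pulses at −120 mbar (−140 to −100 allowed) of
  duration `0.5 + 0.2 k` seconds for attempt `k`, separated by 2 s pauses,
  bounded by 180 s of phase time. Success records the series resistance;
  an access resistance above 100 MΩ is still counted as a failed attempt,
  recorded as `BREAKIN_FAIL` with the measured value, since such
  recordings are not usable.
* **Cleaning** (two calibrated baths): Alconox — −300 mbar for 4 s, five
  +1000/−300 mbar alternations of 1 s each, +1000 mbar for 10 s; then
  aCSF — +1000 mbar for 10 s; then return. Setpoints never leave
  {−300, 0, +1000} mbar.
* **Harvesting** (whole-cell only): −40 mbar for 60 s, −60 mbar for 150 s
  (within the protocol's 2–3 min), −40 mbar for 60 s.

Every phase transition, pressure command and resistance read is logged with
its simulation time; `diary_append()` serializes attempts as JSON lines and
`generate_report()` aggregates outcomes and per-phase durations. Identical
configuration and seeds give bit-identical attempt records.

# What the tests do and do not show

The suite (and the acceptance script) establishes: exact metric arithmetic;
merging and matching laws on constructed and enumerated instances,
including equivalence of greedy matching with exhaustive assignment on
separated instances; calibration recovery bounds; tracker tolerances on
rendered translations and defocus shifts; protocol bounds (pressure bands
per phase, pulse-duration law, seal deadline, break-in cap, escalation
order) on full simulated traces; end-to-end whole-cell success on seeded
scenarios, including drifting cells closed-loop through the image-based
tracker; and a 20-attempt success count consistent with the configured
60 % sealable fraction under an exact binomial interval.

It does not establish performance on real DIC tissue: the phantoms lack
DIC shear, depth-dependent scattering and tissue deformation; the rig's
seal and rupture constants are stand-ins; and the classical blob detector
is a placeholder for a trained network, whose published real-tissue F1
(near 57–66 %) is far below what the detector achieves on clean phantoms.
Numbers measured here bound the algorithmic machinery, not the biology.

# Problem sizes

Default test and acceptance sizes were chosen for desk-scale runs: pipette
stacks of 80 × 288 × 288 voxels (a 33 µm field at the published 0.115 µm
pixel size; rows/columns are the package's choice), cell phantoms of
40–60 slices at 192–256 px, 20-stack localization suites, 20-attempt
Monte-Carlo runs, and tracking frames of 96 × 96 px.
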