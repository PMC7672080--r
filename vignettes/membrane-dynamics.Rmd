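---
title: "Simulating membrane-protein dynamics across fluorescence imaging modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating membrane-protein dynamics across fluorescence imaging modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`smfsim` simulates a population of *independent* membrane proteins in a 2D
cell geometry.  Independence is a deliberate modelling assumption: at the
expression levels where these experiments operate, protein–protein
crowding is a second-order effect, and it buys exact per-molecule
parallelism.  Motion is purely Brownian — per axis and per step
`dx ~ N(0, 2DΔt)` — with no inertia, no anomalous diffusion and no
time-varying geometry.  Three coefficients cover the biology of
diffusional trapping at an adhesive contact: `D_out` (free membrane),
`D_in` (free inside the contact) and `D_trap` (while bound to a partner).
Binding is first-order (`k_on` inside trapping regions, `k_off` for
release), so the stationary bound fraction inside a contact approaches
`k_on/(k_on + k_off)` — *approaches*, because molecules freshly entering
the contact are unbound, and when the diffusive penetration length
`sqrt(4 D_in / k_on)` is comparable to the contact size the interior
occupancy sits measurably below the two-state value.  The test suite uses
rates where penetration is small when it asserts the closed form.

Compartment borders act in two distinct ways:

- the **cell outline** is impermeable: a step that would exit is
  specularly reflected at the first intersected edge, and cancelled if the
  reflection is still outside (sharp corners).  For axis-aligned
  rectangular outlines with no sub-regions the engine switches to an exact
  triangle-wave fold, which is iterated specular reflection in closed
  form;
- a **contact border** is selectively permeable: a step that changes
  sub-region membership is accepted with probability `P_crossing`,
  otherwise the molecule stays where it was ("bounce").  The move is
  cancelled rather than reflected off the border because cancellation
  preserves the equilibrium free density across the border and is the
  simplest scheme with that property; the logic is isolated in
  `resolve_steps()` so a reflecting variant could be swapped in.  One
  crossing test is applied per step.  `P_crossing` is direction-symmetric;
  whether the physical hindrance is symmetric is unknown, and an
  asymmetric value would change the steady-state enrichment.

Bound molecules still diffuse (with `D_trap`) but are tethered: crossing
attempts out of their trapping region are always rejected while bound.

The per-step operation order is fixed and documented: binding is evaluated
from the *pre-move* region, then the displacement is drawn, then the move
is resolved against the geometry.  The alternative order (move first)
changes nothing measurable at `Δt ≤ 100 ms` for the canonical rates, but a
fixed order is what makes runs bit-reproducible.

## Photophysics

Fluorophores move through `PREACTIVE → OFF ⇄ ON → BLEACHED`.  All
transition probabilities use the exact exponential `1 − exp(−kΔt)`, never
the linear approximation — the FRAP bleach pulse (`4.25 s⁻¹ × 400 ms`)
would be badly wrong otherwise.  Competing exits from ON (switch-off vs
bleach) are resolved by sampling one exponential per channel and keeping
the minimum, which preserves branching ratios at any `Δt`.  Only ON
molecules bleach: ground-state dark fluorophores absorb weakly, and the
convention makes the configured `k_bleach` directly the fitted
fluorescence-loss rate.  Table-style parameter envelopes (switch-on
0.005–5 s⁻¹, switch-off 0–10 s⁻¹, bleach 0.4–4 s⁻¹, activation 1–2 s⁻¹,
`Δt` 2–100 ms) are treated as validated ranges: the configuration layer
warns, but does not refuse, outside them.

Initial fluorophore states match each modality's preparation: dSTORM
starts all-OFF (dyes pumped to a dark state before acquisition), SPT and
FCS sample the blinking equilibrium, FRAP starts all-ON (a non-blinking
fluorescent-protein tag), PAF starts all-PREACTIVE.

Two time discretizations of emission exist deliberately.  The per-step
engine marks a molecule ON for a frame if it is ON at the frame midpoint.
The event-based engine (used for dSTORM detection totals) samples exact
exponential dwell sequences and counts a detection in every frame covered
for at least half its duration; with burst phases uniform this is an
unbiased integer realization of on-time/`Δt`, so the expected detection
total is exactly `N · n_frames · k_on/(k_on + k_off)`.  Sub-frame
blinking is otherwise not modelled.

## Imaging

The PSF is a 2D Gaussian integrated over each pixel with the error
function and truncated at 5σ (truncation error < 1e-5); this conserves
photon flux, which the suite asserts to better than 1e-4.  σ is the
configured quantity; FWHM is derived metadata only, because published
σ/FWHM pairs for these systems are mutually inconsistent and only σ
enters the math.  Noise is Poisson shot noise on expected photons,
times gain, plus Gaussian readout noise around the camera offset — no
EM-gain excess factor, no drift.  Localization is *simulated*, not
performed: a detection is the true position plus per-axis Gaussian jitter
of the stated precision.  Camera constants default to EMCCD-plausible
placeholders (offset 100 ADU, readout 5 ADU, gain 1) and are meant to be
configured; `photons_per_frame` has no canonical published value, so
tests rely on noiseless conservation rather than absolute intensities.

Super-resolved maps are plain integer histograms on a (conventionally
32 nm) grid: one detection, intensity one.  Localization jitter can push
a borderline detection outside the mapped field; conservation therefore
holds exactly for the detections inside the map bounds, and totally when
jitter is disabled.

## Protocols

FRAP and PAF share one engine: fixed-`Δt` stepping, top-hat circular
pulse regions (spot *diameters* are what the protocols specify; a
Gaussian profile would add a parameter with no constraint), and frames
sampled at scheduled times — 10 s baseline at 1 Hz, the pulse, then a
decreasing-rate recovery/decay schedule (2 Hz for 10 s, 0.5 Hz for 20 s,
0.1 Hz for 50 s).  ROI intensity is the count of ON molecules inside the
circle: at these densities PSF blur changes only the edges of the ROI
average, and raw counts keep curve statistics interpretable.  Image
stacks are available separately through `render_frame()`/`write_stack()`.
Curve normalization is an analysis step: FRAP maps baseline to 1 and the
first post-bleach frame to 0; PAF subtracts the baseline and divides by
the post-pulse peak.

FCS parks a Gaussian beam (σ = 0.25 µm) and integrates analytically over
a square detection aperture — each ON molecule inside the square
contributes `photons · exp(−r²/2σ²)`.  Pixel rendering would change
nothing statistically and costs two orders of magnitude more.  The
autocorrelation uses the biased (divide-by-N) autocovariance normalized
by `⟨I⟩²`, then by its first nonzero lag; lag 0 is excluded as shot-noise
dominated (a switch restores it).  For free 2D diffusion the ideal-beam
closed form is `G(τ) ∝ 1/(1 + τ/τ_D)` with `τ_D = σ²/D`.  Two finite-size
effects matter in practice and are documented because they shape the test
design: the canonical 1 µm aperture clips the beam at 2σ and shortens the
*fitted* `τ_D` by ≈ 13% (computed against a numerically integrated
truncated-profile oracle), and finite traces in finite cells leave a
slowly-relaxing baseline in the normalized ACF.  The τ_D-recovery test
therefore widens the aperture to 2.5 µm, averages two 600 s traces per
condition, and fits `A/(1 + τ/τ_D) + B` with a free baseline; it checks
`D = 0.3` against `D = 0.6` (the 1/D scaling pair) because slower
coefficients push the box's slow modes beyond what a desk-scale trace can
average.

dSTORM runs are event-based end to end; positions are frozen (fixation),
and a geometry carrying nonzero diffusion coefficients triggers a warning
rather than an error to leave live-cell PALM extensions open.

## Synthetic data: what it emulates, what it does not

The fixture geometries (`make_fixture_geometry()`) are rectangles with a
polygonized circular or strip contact, pre-filled with the canonical
parameter set (`D_out = 0.3`, `D_in = 0.3`, `D_trap = 0.04` µm²/s,
`k_on = 0.15`, `k_off = 0.015` s⁻¹, `P_crossing = 0.3`, pixel 0.16 µm).
They emulate the *statistical* structure of the real experiments —
trajectory length and diffusion-coefficient distributions, detection
budgets, recovery fractions, ACF decays — under the stated rates and
geometries.  They do not emulate membrane heterogeneity, ruffles,
irregular cell shapes, labeling chemistry, drift, or asymmetric border
hindrance.  A green test therefore establishes internal consistency with
the stated model at the stated parameters, not agreement with any
particular cell.  Two published quantities are explicitly out of reach at
desk scale and are *not* asserted: experiment-vs-simulation correlations
(they need the experimental curves) and the steady-state contact
enrichment of ≈ 3.9 — full trapping equilibrium with symmetric crossing
gives `1 + k_on/k_off = 11`, the published value implies partial
equilibration and/or asymmetries whose details are unstated, so the
package exposes `enrichment_timecourse()` as a diagnostic instead and the
suite asserts the 11 only for a deliberately equilibrated configuration.

## Numerical choices

- Containment is the even-odd rule with on-edge points counted inside
  (deterministic tie-break); a bounding-box prefilter keeps the cost
  proportional to the points near each polygon.
- Pixels are half-open: pixel `(i, j)` covers
  `[i·s, (i+1)·s) × [j·s, (j+1)·s)`, origin at the raster's top-left
  corner, x rightward, y downward.  No half-pixel offsets anywhere.
- Diffusion-coefficient estimation follows the standard SPT recipe:
  ordinary least squares on the first 4 MSD points with a free intercept
  (which absorbs the `4σ_loc²` localization offset), `D = slope/4`,
  trajectories longer than 20 frames, and a floor of `1e-5` µm²/s for
  trajectories whose net displacement is below the localization
  precision or whose fitted slope is non-positive.
- One root seed is split into named subsystem streams (motion,
  photophysics, imaging) via a multiplicative hash, so changing the
  localization noise does not perturb trajectories; the suite asserts
  this.  Splitting per molecule, as a per-thread engine might, would
  defeat R's vectorization and is intentionally not done.
- The `.trc` export is the 5-column tracker-style layout (trajectory,
  frame, x px, y px, intensity) at 6 decimals; the format name fixes only
  the extension, so the layout is documented here and covered by a
  round-trip reader.
- TIFF stacks are written by a minimal baseline TIFF 6.0 codec
  (little-endian, uncompressed, 16-bit grayscale, one strip per page)
  because no TIFF package is available in the supported environment; it
  was cross-checked against an independent Python reader during
  development and is covered by round-trip tests.
- The activation-rate parameter is named `k_activ` for what it does
  (PREACTIVE → switchable), sidestepping the inconsistent superscript
  naming that sometimes labels it like a decay rate.

## Known limitations

2D only; Brownian only; one bound state; no inter-molecule interactions;
no EM-gain noise statistics or drift; localization is jitter, not
fitting; compressed/tiled TIFFs are not read.  These map to the
documented non-goals of the design rather than to missing engineering.
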