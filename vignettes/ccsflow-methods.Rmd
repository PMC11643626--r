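---
title: "Quantifying intracellular flow and cell stiffness with ccsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular flow and cell stiffness with ccsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsflow)
```

`ccsflow` turns two kinds of raw measurements into biophysical numbers:
time-lapse movies of punctate fluorescence (clathrin-coated structures,
cortical actin) into flow fields, radial speed profiles and direction
statistics; and AFM nanoindentation curves into Young's moduli. This
vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The measurement problem

In adherent cells such as *Drosophila* hemocytes, clathrin-coated
structures are advected by the actin cytoskeleton: in healthy cells they
stream centripetally from the margin toward the cell center, while
perturbations of actin dynamics (or the presence of protein aggregates)
stall them. Two complementary estimators quantify this. Particle image
velocimetry (PIV) measures the collective, continuum flow field by
cross-correlating image windows between frames; single-particle tracking
follows individual puncta. PIV averages the displacement of everything in
a window, so it systematically *underestimates* per-particle speeds, but
it is robust at high density and reveals the large-scale flow topology;
tracking is more precise per object but needs identifiable, separable
puncta. `ccsflow` implements both and the package's tests assert the
expected inequality between them.

## Drift correction

Stage drift moves the whole cell relative to the camera and would be read
as flow. Frames are registered translation-only: consecutive frames are
phase-correlated (cross-power spectrum whitened, 3-point subpixel peak)
and the interframe shifts are accumulated into each frame's displacement
relative to a reference frame, then removed by bilinear resampling with
zero fill. Two choices deserve comment:

* **Translation only.** Center-of-mass drift is translational; rotation of
  an adherent cell on the stage is rare on these time scales, and a
  rotational term would couple into the radial statistics we are trying to
  measure. Rigid-body registration is deliberately out of scope.
* **Consecutive frames, not a fixed reference.** A punctate movie with
  little static structure decorrelates from a distant reference frame
  (every punctum has moved), and a whitened spectrum then amplifies noise
  into spurious peaks. Consecutive frames always overlap strongly. The
  per-step peak search is bounded at `min(H, W)/4` px; the accumulated
  estimate for a genuinely drifting movie is unaffected.

## Static-background intensity correction

Writing the recorded movie as `I0(i,j,k) = S(i,j) + M(i,j,k)` — a static
part (immobile puncta, out-of-focus pool) plus a moving part — the static
term contributes a zero-displacement peak to every correlation window and
drags PIV toward zero. The correction subtracts the temporal mean frame
with clipping:

`Ic(i,j,k) = max(0, I0(i,j,k) − Imean(i,j))`,  `Imean = (1/N) Σₗ I0(·,·,l)`.

Any temporally constant pixel maps to exactly zero. For a pixel lit in a
single frame out of `N`, the corrected value is exactly `(N−1)/N` of its
moving intensity, and in general the moving pattern is preserved up to
this mild attenuation — the tests assert a rank correlation above 0.9
between original and corrected patterns on signal-carrying pixels of
static-free movies. The correction degrades when dynamics are slow (a
pixel lit for many frames donates much of itself to the mean); this is
inherent to the method and is one reason the PIV post-processing chain
exists. The order matters: drift correction must come first, because
drift turns static structures into apparent motion.

## PIV

`compute_flow_pair()` estimates the displacement field between two frames
by windowed FFT cross-correlation with coarse-to-fine refinement:

* **Pass schedule** 512 → 128 → 64 px at 50% overlap. The end points
  follow standard practice for these movies; the intermediate size is a
  geometric-style step and is configurable. A first window larger than
  the frame is shrunk to the largest power of two that fits (with a
  warning).
* **Window offsetting vs deformation.** Later passes seed each window's
  position in the second frame with the displacement interpolated from
  the previous pass (integer offset). Full bilinear image deformation
  between passes is available (`deform = TRUE`); for the small
  displacements of intracellular flow (≤ 1 px/frame) offsetting is
  sufficient and cheaper.
* **Subpixel peak** by the 3-point Gaussian estimator, falling back to a
  parabola when a log is undefined. Windows with zero variance or centered
  outside the mask yield invalid (flagged, never zeroed) vectors.

Post-processing per frame pair, in order: (1) a global filter removing
vectors more than 4 SD from the field mean (per component); (2) a local
filter removing vectors whose residual to the 3×3 neighbourhood median
(center excluded) exceeds 4 px/frame plus an epsilon floor of 0.1 px/frame
— the epsilon keeps the filter from firing on numerically tiny residuals
in near-uniform fields; (3) Laplace (spring) interpolation of missing
vectors from their valid neighbours; (4) one pass of 3×3 mean smoothing.
With fewer than 4 valid vectors, interpolation is refused and the field
returned flagged.

The time average `V(i,j) = ⟨v(i,j,k)⟩` uses, at each grid point, only the
frame pairs where that point was valid, and marks the averaged point valid
only if at least half the pairs contributed. This keeps transiently
occluded regions from biasing the steady-state field.

**Known sensitivity.** Halving the final window to 32 px leaves the radial
profile's sign and shape intact but dilutes `|Vr|` by 10–20% on synthetic
movies: at punctate densities of a few spots per 32-px window, a larger
fraction of windows is noise-dominated, and their near-zero vectors pull
the time average toward zero. Denser real movies are less affected. The
package tests assert shape and sign stability with a 25% magnitude band.

## Radial profiles and direction histograms

About the cell center `(xc, yc)` — by default the intensity-weighted
centroid of the movie's time-maximum projection inside the mask — each
valid vector is projected onto polar coordinates:
`Vr = Vx cos θ + Vy sin θ` (outward positive, so centripetal flow is
negative) and `Vθ = −Vx sin θ + Vy cos θ`. `Vr` is averaged over annuli of
width Δr = 60 px; with a pixel size of 0.1 µm/px that is 0.5–1.2 µm of
cell radius per annulus, a few annuli per cell. Annuli with no vectors
carry `NA`, never zero. Plots report the speed `|Vr|`; the sign is kept in
the data. The circular-cell approximation (concentric annuli rather than
boundary-following contours) does not change the nature of the flow field
and is retained.

The direction histogram bins `θ_dir = θ_v − θ` (velocity direction minus
outward polar direction, wrapped to [0°, 360°)) into 24 equal bins
**centered** on 0°, 15°, …, 180°, … — the first bin wraps across 0°/360°.
Centering matters: the canonical signatures (0° outward, 180° inward, ±90°
circular) would otherwise sit exactly on bin edges, splitting a sharp peak
between two bins and making "the modal bin" ambiguous. Zero-magnitude
vectors are excluded (no defined direction), as is a vector exactly at the
center (no defined polar direction). Vectors are not weighted by magnitude
by default (`weight = "magnitude"` is available); an unweighted histogram
answers "which way is traffic heading" independently of how fast.

## Tracking, velocities, kymographs

Spots are detected per frame with a single-scale Laplacian-of-Gaussian
filter (scale = expected punctum σ, default 1.5 px), local maxima above a
relative threshold, and 5×5 centroid refinement to subpixel precision.
Linking is greedy mutual-nearest-neighbour within `max_disp` px/frame
(ties by smallest displacement, then lowest id), with optional gap closing
(`memory` frames, proportionally enlarged radius). This is deliberately
simple: at the low densities and short displacements of CCS movies it
links > 90% of steps correctly on ground-truthed synthetic data, and its
failure mode (track fragmentation) biases velocity statistics far less
than wrong links would.

The mean instantaneous velocity of a track is the mean over consecutive
observations of step length divided by step duration (µm/s) — the natural
per-object counterpart of the PIV speed. Tracks shorter than 3 frames are
excluded from velocity summaries as a noise guard. Radial displacement
series `r(t) − r(0)` are negative for net inward movement. Kymographs
sample intensity along a fixed line (default 3 px perpendicular
averaging): rows are time, columns distance, so stalled puncta draw
vertical lines and moving puncta oblique streaks whose slope is the
speed.

## AFM nanoindentation

An approach curve records cantilever deflection `d_cant` against piezo
displacement `d_pz` (both in metres after sensitivity conversion). Force
and sample deformation follow as `F = k·d_cant`, `δ = d_pz − d_cant`. The
Sneddon rigid-sphere-on-elastic-half-space model, parameterized by contact
radius `a`,

`F(a) = E/(1−ν²)·[(a²+R²)/2·ln((R+a)/(R−a)) − aR]`,
`δ(a) = (a/2)·ln((R+a)/(R−a))`,

is inverted per depth by bracketed root-finding on `[0, R)` (relative
tolerance 1e−10; `δ(a)` diverges as `a → R`, hence the hard requirement
`max_depth < R`). In the shallow limit it reduces to the Hertz sphere
formula `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}` — verified to 1% at `δ ≤ 0.01 R`.

Because `F` is linear in `E`, the modulus fit is exact linear least
squares against the unit-modulus model force — no iterative optimizer, no
starting values. Everything difficult lives in the contact point:

* The pre-contact baseline is linearly detrended (provisional first-20%
  window, then re-estimated on the accepted pre-contact region — one
  iteration; at high stiffness the fixed window can overlap the contact
  rise).
* Each candidate contact position `z₀` splits the curve into a flat zero
  baseline before and a best-fit Sneddon rise after; the summed residual
  is minimized coarse-to-fine over samples, then refined continuously
  between samples (golden-section via `optimize`). Force is referenced to
  the baseline level, not to the noisy sample at `z₀` — the model itself
  pins `F(contact) = 0`, and anchoring to one sample injects its noise
  into every residual.
* A curve that never rises a set multiple (default 5) of the baseline
  noise above the baseline is reported as "no contact".

With both `E` and `z₀` unknown, contact precision at force SNR 20 is
limited to roughly a few sample spacings (~10–20 nm median on synthetic
sweeps; near the joint estimation bound). Noiseless curves recover the
contact within one sample and `E` to better than 0.1% across 0.1–100 kPa.
Defaults mirror common practice for cell nanoindentation with a beaded
lever: R = 2.5 µm (5 µm glass bead), k = 0.2 N/m, ν = 0.5
(incompressible), fit depth ≤ 500 nm. Only the approach segment is
fitted; retract analysis (adhesion) and viscoelastic models are out of
scope. A cell measured on an n×n grid is summarized by the median of its
per-curve moduli — robust to the occasional curve landing off the cell or
on a stiff organelle.

## FRAP

Recovery traces are double-normalized: background-subtracted ROI divided
by background-subtracted whole-cell reference (cancelling acquisition
photobleaching and gain drift), scaled so the pre-bleach mean is 1. A
single-normalization variant is selectable. Recovery is fitted post-bleach
as `I(t) = I0 + A·(1 − exp(−t/τ))` (Levenberg–Marquardt); the mobile
fraction is `(plateau − floor)/(1 − floor)` with the fitted `I0` as floor,
and the half-time is `τ·ln 2`. Raw mobile fractions outside [0, 1] are
clamped and flagged rather than silently truncated. Timing defaults match
the acquisition the package emulates: 15 pre-bleach frames and 50
post-bleach frames at 5.66 s.

## Synthetic data: what it does and does not show

The generators exist so every stage can be tested against known ground
truth without raw microscopy data. `generate_ccs_movie()` renders puncta
as isotropic 2D Gaussians (σ = 1.5 px) on a constant baseline, advects the
mobile subset by the flow model (centripetal speed profile: linear ramp
from 0 at the center to the set speed at the cell radius, reflecting that
radial speed peaks near the margin), keeps a static subset as the
background pool, and adds Poisson shot noise (optionally Gaussian read
noise, optionally whole-field exponential photobleaching). Ground-truth
tracks obey the update rule exactly before any pixel noise. All
randomness flows from one explicit seed per call; the same seed is
bit-identical.

Not emulated: pit nucleation/maturation kinetics (puncta neither appear
nor disappear), anisotropic or depth-dependent PSFs, camera gain/offset,
intensity heterogeneity between puncta, non-circular cells. Consequently,
a passing pipeline demonstrates correctness of the estimators under
idealized punctate signal — it does not certify performance on movies
whose difficulty comes from those unmodeled features. Defaults (100
puncta, 30% static, amplitude 100 photons over baseline 10) were chosen
once as plausible for punctate live-cell imaging; they are free
parameters, not values calibrated to any particular dataset.

Problem sizes used by the package's own checks: unit fixtures of
64–256 px; end-to-end runs on 256×256×40 and 512×512×60 movies (the
latter matching the acquisition geometry the pipeline targets: ~5 min at
5 s intervals); 50-curve AFM noise sweeps. The full test suite runs in
about two minutes on one core.

## Numerical conventions

Images are `[row, col, frame]` with y increasing downwards; positions are
`(x, y) = (col, row)`; angles from `atan2(y, x)` — all direction
statistics are internally consistent, and θ_dir, being a *relative* angle,
is independent of the y-axis convention. Internal units are px and
frames; every user-facing quantity is converted to µm and seconds via the
movie calibration. Intensities are processed in double precision
regardless of input bit depth. Movies are written as 32-bit float TIFF
pages scaled to [0, 1] with a JSON sidecar carrying pixel size, frame
interval and the intensity scale, so round trips are exact to float32
precision.
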