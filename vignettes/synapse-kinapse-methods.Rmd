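---
title: "Methods: quantifying synapse versus kinapse behaviour of T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synapse versus kinapse behaviour of T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkin)
```

## The problem

When a T cell meets a stimulatory surface it can signal in two modes: a
*stable synapse*, in which the cell spreads symmetrically and its centroid
barely moves, or a motile *kinapse*, in which the cell keeps crawling while
signalling. `synkin` quantifies this dichotomy from time-lapse centroid
tracks and segmented cell masks, and measures how durably cells interact
with spatially restricted stimulatory spots (micro-contact-printed anti-CD3
disks, 10 or 20 µm wide on a 30-µm square lattice, emulating the spacing of
antigen-bearing dendritic cells in a lymph node).

Tracks enter as tidy CSV (`cell_id, frame, time_s, x_um, y_um` plus optional
per-frame channels such as a calcium ratio); masks as per-frame binary
rasters with a known pixel size. Segmentation and tracking themselves are out
of scope — upstream tools produce the tables this package consumes.

## Confinement score and the positional stability index

Speed alone demarcates arrest poorly: T cells move in a narrow speed range
with abrupt fluctuations. Instead we use a transient-confinement score of
the Simson–Saxton type, developed for single-particle tracks of membrane
proteins. For a sliding window of duration $t$ centred on each frame, let
$r$ be the maximum displacement from the window's first position and $D$ the
cell's free-motion diffusion coefficient. The probability that free
diffusion would stay that confined is approximated by

$$\log_{10}\psi \;=\; 0.2048 \;-\; 2.5117\, \frac{D\,t}{r^2},$$

clipped to $(0,1]$. Two properties matter:

* Evaluated at the *observed* excursion radius, $\psi$ is approximately a
  probability integral transform: near-uniform on pure Brownian tracks.
  This is what makes the threshold a chance probability. (An earlier draft
  used half the maximum pairwise displacement as the radius; the null
  false-positive rate was then ~0.5 rather than ~0.017, so the excursion
  radius — the statistic the relation was calibrated on — is used instead.)
* The decay constant $2.5117 = j_{01}^2/\ln 10$ is the continuous-diffusion
  asymptotic of the disk stay-probability; a track sampled at 30-s frames
  "overstays" slightly, which is why the Monte-Carlo oracle in the test
  suite samples Brownian paths with 200 substeps per window. Formula and
  simulation agree within ±30 % for $Dt/r^2 \lesssim 0.8$ (ψ ≳ 0.015) —
  the calibrated regime bracketing the decision threshold.

$\psi$ maps to the score by the fixed transform $L = \max(0, -\ln\psi - 1)$,
so the demarcation threshold $L > 3$ corresponds to $\psi < e^{-4} \approx
0.018$, matching the printed chance bound of < 0.017 within rounding. The
log base of the original method is ambiguous; this transform is an
interpretation, chosen exactly because it reproduces that bound, and both
the threshold and the transform cap (`L_max = 10`) are arguments.

Per-frame $L$ averages window lengths {10, 15, 20, 25, 30} frames (the
source publication does not state its windows; a spread of windows makes the
score robust to bout length). Frames where no full window fits score 0 —
track ends are never called confined.

**Demarcation and edge correction.** Runs of $L > 3$ lasting at least
`min_duration = 10` frames (5 min at 30-s frames — suppresses single-frame
flickers) become confined periods. Because windows are centred, a window
straddling a bout edge picks up free motion and scores low, eroding each
true bout by up to half a window per side. Each run is therefore extended
frame-by-frame while the position stays inside the core run's confinement
zone (its excursion radius about its centroid, +1 µm slack), capped at half
the largest window per side. Blind fixed padding was rejected: it swallows
kinapse excursions, inflates the period's spatial extent and flips genuinely
stable periods to unstable.

**Stability call.** Each confined period of duration $t$ frames and confined
zone diameter $R$ (maximum pairwise displacement — here the diameter
definition *is* the right one) has positional spread $R^2/t$; spread below
**0.666 µm²/frame** marks positional stability (synapse). The **positional
stability index (PSI)** is the fraction of frames inside stable periods;
PSI > 0.5 means majority-synapse behaviour.

**Diffusion coefficient.** $D$ comes from an origin-constrained least-squares
fit of the time-averaged MSD over lags 1–4 frames, floored at $10^{-6}$
µm²/s. For mixed tracks this upper-bounds the free-motion $D$, which is the
conservative direction. A cell that never leaves confinement carries no
information about its own free motility — its short-lag MSD is only the
confined jiggle — so `psi_table()` floors each track's $D$ at the cohort
median (`pool_D = TRUE`): cells imaged together share conditions. The
single-track API keeps the pure per-track estimate.

## Spot interactions and the half-life of interaction

A spot grid is a square lattice (`build_spot_grid`): disks of diameter 10 or
20 µm spaced 30 µm centre-to-centre. **Arrest** is called operationally: at
least 10 frames of continuous occupancy of one spot with smoothed speed
below 2 µm/min (arrest is an operational call with no canonical threshold;
both numbers are arguments). The attach frame is walked back over occupied frames whose
arrival step is already slow, compensating the smoothing lag. **Exit**
requires the centroid to stay beyond the spot radius plus a 2-µm hysteresis
margin for 10 frames — protrusive wobble across the spot edge is not a
departure. Cells still attached when the movie ends are censored at the
horizon. Later arrests of the same cell (typically on a neighbouring spot)
are tallied as re-engagements and excluded from survival, as in the source
analysis.

**Survival.** The percentage of initially arrested cells still on their
original spot is tallied in 15-min bins of time-since-own-attachment (a
censored cell counts as remaining until its horizon, then leaves the
denominator; the curve is forced non-increasing). Under first-order exit
kinetics $\ln(\%)$ is linear in time and the **half-life is
$\ln 2/|\mathrm{slope}|$**. Bins are weighted by the inverse sampling
variance of $\ln S$ (∝ $S/(1-S)$): with equal weights the late, sparse bins
dominate the fit error, and the estimator then misses the package's own 10 %
recovery criterion on a noticeable fraction of seeds (`weights = "equal"`
restores the plain fit). Zero decay over the horizon reports `Inf` with a
`no_decay` flag; a curve that empties in the first bin refuses to fit.

**Virtual synchronization** re-indexes any per-frame channel (calcium ratio,
projected area, smoothed speed) to time-since-own-arrest and averages across
cells, reproducing the aligned calcium/arrest/spreading overlays around spot
engagement.

## Mask metrics on spots

*Sampling efficiency*: over a sliding 20-frame (10-min) window, the number
of unique pixels ever covered by the cell footprint divided by the
footprint pixel counts summed with multiplicity. A stationary cell scores
exactly $1/20$; pairwise-disjoint footprints score 1. "Unique over total" is
interpreted as union over sum-with-multiplicity — the interpretation that
makes those two limits exact. The track-level value averages sliding
windows (stride 1, configurable).

*Protrusion index*: per frame, with cell and spot rasterized on the same
grid (pixel-centre inclusion, no sub-pixel correction; < 2 % area error at
the tested resolutions), fractional overlap $f = |cell \cap spot|/|cell|$
and maximum possible overlap $m = \min(1, |spot|/|cell|)$ give the index
$m - f \in [0,1]$ — the cell area extended beyond the spot, corrected for
cells too large to overlap fully. Pooled $(\text{area ratio}, f)$ points
form the overlap contour with the boundary trace $m(\rho) = \min(1, 1/\rho)$;
the vertical distance from the trace is the protrusion index. The contour's
abscissa (absolute area vs ratio) is not stated in the source; the area
ratio is adopted because it makes the boundary trace a single curve.

## The synthetic world

The generators state the world once; their defaults are not tuned to tests.

* `simulate_two_state_track`: alternating exponential dwells between a
  kinapse mode (persistent random walk: heading diffuses with variance
  $2\Delta t/\tau_p$ per step, $\tau_p$ = 120 s, speed 8 µm/min) and a
  synapse mode (Gaussian steps, per-axis sd = radius/8, reflected inside a
  2-µm-radius zone anchored at the entry point). 30-s frames, 240 frames
  (2-h movies). Speed and cadence magnitudes mirror the imaging regime the
  analysis targets; only the structure, not these numbers, is claimed from
  any experiment. Ground-truth per-frame labels are emitted, so every
  recovery test scores against the realization's true label fraction, not
  the nominal dwell fraction.
* `simulate_brownian_track`: i.i.d. Gaussian steps, per-axis variance
  $2D\Delta t$ — the null model of the confinement score.
* `simulate_residence_times`: exponential lifetimes at rate
  $\ln 2/t_{1/2}$, censored at the horizon, attach at $t = 0$ (imaging
  starts once spots are occupied).
* `render_mask_movie`: disks rasterized by pixel-centre inclusion along a
  track; `simulate_spot_engagement`: a scripted approach–arrest(–exit)
  trajectory with a planted calcium step, for arrest-detection and
  synchronization tests.

What the generators do **not** emulate: cell shape beyond disks, signalling
dynamics beyond a step channel, spot crowding, drift or segmentation noise.
A green recovery test therefore establishes that the estimators recover
planted truth under the stated stochastic structure — not that biological
effect sizes are reproduced. In particular the donor-level headline numbers
of the motivating experiments (naive vs memory half-lives of hours) derive
from undeposited movies; the demo cohorts plant such values as generator
inputs only.

## Numerical choices and degenerate inputs

* ψ is floored at $e^{-(L_{max}+1)}$ so zero-spread windows (a perfectly
  stationary cell) give the capped score rather than dividing by zero.
* Frame gaps are preserved; all speeds and MSDs use true time differences.
* Smoothed speed averages the instantaneous step speeds of the two frames
  before and after the frame in question, truncated at track ends; a
  single-point track is an error, not zero.
* The PSI-recovery world plants dwell fractions with a one-hour mean cycle
  (`dwell_synapse = f·3600 s`), keeping bouts resolvable above the 10-frame
  minimum duration.
* Survival curves with a positive fitted slope (possible in tiny samples)
  report `no_decay` and an infinite half-life rather than a negative one.
* Group comparisons refuse n < 3 and zero-variance paired differences; the
  Mann–Whitney p is exact for small tie-free samples (it equals exhaustive
  permutation enumeration in the tests) and normal-approximated with ties.

## Known limitations

* The ψ→L transform reproduces the printed threshold bound but the original
  publication's exact numeric path is not derivable; both are configurable.
* Per-track $D$ makes the score *relative to each cell's own motility*; the
  cohort floor mitigates, but a cohort that is entirely synaptic would still
  under-detect. This is an identifiability limit, not an implementation one.
* Percent-remaining fitting is not Kaplan–Meier; it matches the source
  method and is appropriate at the tested censoring levels (≤ 12.5 %), but
  heavier censoring would bias it.
* Mask metrics assume a shared raster per cell and pixel-centre
  rasterization; very coarse pixels (> ~1 µm on a 10-µm spot) would need
  sub-pixel treatment.
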