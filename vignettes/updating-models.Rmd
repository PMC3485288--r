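---
title: "Dissociating spatial-updating models with dynamic double steps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating spatial-updating models with dynamic double steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazestep)
```

## The scientific problem

When the eyes and head reorient gaze with a rapid saccadic shift, any
visual target flashed around that movement lands on the retina at a
location that no longer corresponds to where the target is in space once
the movement ends. Accurate behavior therefore requires *spatial
updating*: the stored target location must be compensated for the
intervening movement. The double-step paradigm probes this directly: two
brief flashes (T1, then T2) are presented in darkness and the subject must
foveate both in sequence. In *static* double steps T2 appears while gaze
still rests at the fixation point; in *dynamic* double steps T2 appears in
midflight of the first gaze shift, so its retinal error depends on the
instantaneous gaze position at an unpredictable moment.

Three conceptual schemes can, in principle, produce accurate second gaze
shifts, and they are distinguished by what signal is subtracted from the
retinal error of T2 (written `T2E`, the eye-centered target location at
flash time):

* **VU — visual feedforward updating**: uses only retinal vectors,
  `dG2 = T2E - T1E`. It cannot compensate mislocalizations of the first
  gaze shift.
* **SFB — static motor feedback**: subtracts a corollary discharge of the
  *entire planned* first gaze shift, `dG2 = T2E - dG1`. In dynamic trials
  this overcompensates by the displacement already completed when T2
  flashed.
* **DFB — dynamic motor feedback**: subtracts only the *remaining* motor
  error at flash time, `dG2 = T2E - GME1` with `GME1 = G2 - G1` (gaze
  position at second-shift onset minus gaze position at T2 onset).
  Equivalently, gaze-position feedback: `dG2 = (T2E + G1) - G2`. The two
  forms are algebraically identical and cannot be dissociated behaviorally;
  the package treats them as one model and verifies the identity in tests.

A **NC** (no compensation) benchmark, `dG2 = T2E`, anchors the comparison.

The models are fitted per response component (azimuth, elevation) by
multiple linear regression, `dG2 = alpha * T2E + beta * X + bias` with
`X ∈ {T1E, dG1, GME1}`; ideal updating corresponds to `alpha = +1`,
`beta = -1`, `bias = 0`. Models are compared by the coefficient of
determination, defined throughout as the squared Pearson correlation
between observed and fitted values (this matters: under forced ideal
coefficients it differs from `1 - SSE/SST`). Confidence limits come from a
1000-resample row bootstrap; competing models are refitted on the *same*
resamples so their per-replicate r² values can be compared with paired
t-tests. That procedure is anti-conservative (replicates are not
independent experiments) and is flagged as such; it is retained because it
is the field's stated practice.

## Coordinates and conventions

Targets live on a web of 7 eccentricity rings (5–43 deg) by 12 directions
plus the center (85 positions). All analysis uses the double-pole chart:
azimuth is the angle from the median plane, elevation from the horizontal
plane, via `azimuth = asin(sin R cos phi)`, `elevation = asin(sin R sin phi)`.
This transform preserves eccentricity (verified against a 3D unit-vector
oracle to < 1e-9 deg) and degenerates correctly on both meridians.
Displacements, errors and regressions are component-wise in this chart,
treated as locally flat; full 3D rotation kinematics (noncommutativity,
torsion) are out of scope. Positions are up-positive everywhere; only the
raw localization-error metric (`localization_error()`) uses the
screen-reading convention in which positive vertical error means ending
*below* the target, and `to_under_overshoot()` converts such errors to
signed under-/overshoots.

## What the simulator emulates

`simulate_session()` generates trace-level sessions: 2D gaze and head
position signals at 1017.25 Hz. Its defaults are the paradigm's stated
conditions:

| parameter | default | meaning |
|---|---|---|
| fixation duration | 600–1100 ms | uniform, integer ms |
| gap 1 | 10–70 ms | fixation offset to T1 onset |
| flash durations | 10–30 ms | integers |
| gap 2 | 90–140 ms | T1 offset to T2 onset |
| single-step fraction | 56% | keeps the subject from waiting for T2 |
| first-saccade gain | 0.9 | the typical ~10% undershoot |
| endpoint scatter | 3 deg/component | magnitude of measured endpoint SDs |
| fixation jitter | 0.5 deg | inside the 8-deg fixation window |
| first-saccade latency | 141 ± 30 ms | Gaussian, truncated at 60 ms |
| second-saccade latency | lognormal, median 180 ms | after T2 onset; never before the first shift ends |
| main sequence | 20 ms + 1.5 ms/deg | amplitude–duration line |
| head recruitment | 0.4 × (A − 10 deg), SD 3 deg | head contribution grows above threshold and varies strongly between trials |
| head lag | 30 ms | head starts after the eye |
| VOR gain | 1 | gaze pinned while the head completes its movement |

Movement profiles are raised-cosine (velocity `∝ 1 − cos`), chosen because
they are smooth, have closed-form position and peak speed (`2A/D`), and the
source experiment specifies no profile. Latency means/SDs are taken from
the printed first-saccade latency distributions; the second-saccade
latency distribution is not printed anywhere, so a lognormal with median
180 ms was chosen once as a realistic reaction-time shape. The timing
chain (gap 2 vs first-saccade latency) naturally produces both static and
dynamic trials in one session, exactly as the paradigm intends.

A fraction (15%) of simulated double-step responses skips T1 and goes to
T2 with a single saccade; these exercise the analysis's rejection path.
Curved single-saccade responses (the other discard category in real data)
are *not* generated — the original analysis discarded them because the
transition point is not well defined, and the pipeline's exclusion
machinery is fully exercised without them.

`simulate_records()` is the record-level tier: it evaluates the same
kinematic model in closed form (profile position at T2 on/offset, gain,
scatter, jitter) and directly emits the per-trial regression record. It
exists because recovery experiments need hundreds of replicate sessions
with hundreds of dynamic trials each; running the trace pipeline for those
would only re-test detection, which has its own dedicated tests. The two
tiers are linked by tests asserting that trace-level extraction reproduces
the closed-form ground truth.

What the simulator does **not** emulate: measurement noise of the coil
recording system, saturating peak-velocity main sequences,
oblique-component cross-coupling, torsion, and online reward logic. A
consequence worth stating plainly: passing recovery tests show the
*analysis chain* is correct and identifiable under realistic noise — they
do not show that real monkey data would be this clean.

## Event detection and screening

Traces are low-pass filtered (linear-phase FIR, Hamming window, cut-off
75 Hz, order 50). The filter is applied in a single pass and shifted by
its exact group delay (order/2 samples) so event times are unshifted; a
forward-backward option exists but squares the magnitude response and
visibly rounds movement corners. Edges are padded by replication to avoid
end transients. Taps are normalized to unity DC gain.

Saccades are detected with velocity thresholds: preliminary onset when 2D
vectorial gaze speed exceeds 100 deg/s, preliminary offset when it next
drops below 70 deg/s. Markers are then refined "toward the nearest drop
below zero acceleration", which is ambiguous as stated; the package
resolves it as: onset moves *backward* to the latest sample with
acceleration ≤ 0 (the base of the speed rise), offset moves *forward* to
the earliest sample with acceleration ≥ 0 after the deceleration. The
search is bounded to 50 ms around the preliminary marks, and events closer
than 10 ms are merged. On noise-free synthetic shifts this places markers
within ±1.3 ms of ground truth and amplitudes within 0.8%.

Detected saccades are screened against the amplitude–duration main
sequence: a least-squares line is fitted over the session and events with
residuals beyond twice the residual SD are discarded in a single pass
(not iterated — the source procedure describes one pass, and the 2 SD
outlier cut in the regressions below is likewise applied once). When the
events lie exactly on a line the residual SD is numerically zero and
nothing is discarded.

## Per-trial records and exclusions

For each double-step trial the pipeline identifies the first response (the
earliest saccade after T1 onset) and the localization response (the last
saccade starting before the closed-loop reappearance of T2); one-saccade
trials are rejected. Trials whose T2 flash outlasted the first gaze shift
are excluded (possible direct visual feedback); the boundary is strict
(`offset > offset` excludes, equality keeps). Trials are classified by
gaze movement during the flash, measured as *path length* (a net-displacement
option exists): < 0.5 deg static, > 5 deg dynamic, the gap in between —
which the printed criteria leave undefined — is excluded as intermediate,
the only reading consistent with both thresholds being definitions.

The record carries: `T1E`, `T2E` (retinal target locations at flash
times), `dG1`, `G1`, `G2`, `GME1 = G2 − G1`, `dG2`, `GME2`, `HME2`, `dH2`
(head displacement from second gaze-shift onset to its offset), streak,
delay and flash duration. The second head-movement onset needed for `HME2`
has no stated criterion in the source experiment; the default takes the
head position at the second gaze-shift onset, with a 20-deg/s head-speed
crossing rule available as configuration.

## Head-movement analysis

`fit_head_mlr()` regresses `dH2` on `GME2` and `HME2` (azimuth only by
default — head movements are predominantly horizontal). A dominant `HME2`
weight means the head is goal-directed in head-centered coordinates, which
requires eye-in-head position information; a dominant `GME2` weight would
mean the head simply follows the gaze error. The two regressors are
substantially correlated (they differ by eye-in-head eccentricity), so the
fit flags near-collinearity; trial-to-trial variability of the head
contribution — a robust feature of head-unrestrained gaze shifts — is what
makes the regression identifiable, and the simulator includes it (SD 3 deg).

## Perisaccadic error analyses

Residual errors of the second gaze shift (after full dynamic updating) are
decomposed into components parallel and perpendicular to the first
gaze-shift vector, and examined against flash delay and flash duration
(running mean over a 25-ms window stepped by 5 ms, minimum 10 trials —
widths chosen here, none are stated in the source). Under DFB behavior
both trends are flat. Under SFB behavior the parallel error equals minus
the pre-flash gaze displacement, so its slope against that displacement is
−1: the overcompensation signature that dissociates the two motor-feedback
models. Note the sign: with errors defined as response minus updated
target and the parallel axis along the first gaze shift, overcompensation
is *negative*.

## Numerical and design choices

* Regressions use QR least squares (`lm.fit`); r² is the squared Pearson
  correlation of observed and fitted values.
* The 2 SD outlier cut runs once, then the fit is recomputed on survivors.
* Bootstrap resamples are drawn at the row level; rank-deficient resamples
  are redrawn (up to 100 times, counted); model-comparison bootstraps share
  resample indices across models within a replicate so the r² t-tests are
  genuinely paired.
* All-static record sets make `dG1` and `GME1` identical, so SFB and DFB
  fits coincide to machine precision — reported as a tie, never broken
  arbitrarily.
* Randomness is controlled by a single session-level seed; every
  stochastic draw derives from it, making trial tables and record tables
  byte-identical across runs.
* Degenerate inputs: zero-variance regressors are flagged, the pole of the
  polar chart maps to `phi = 0`, single-sample streaks are 0, and
  decomposition onto a zero-length reference vector raises an error.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
generated at run time: sessions of 80–400 trials for trace-level checks,
100 replicate sessions of 1500 double-step records per ground-truth model
for the recovery experiment (each containing ≥ 300 classified dynamic
trials), n = 500 records for the noisy-fit and head-regression checks,
1000 bootstrap resamples, and 1000 repeats for the KS type-I calibration.
These sizes were chosen to keep every statistical claim at the scale it
needs while the whole suite runs in well under an hour on one core.

## Known limitations

* The chart is treated as locally flat; at 43-deg eccentricities the
  component-wise arithmetic ignores spherical curvature, exactly as the
  source analysis does.
* Eye-in-head position is the linearized difference gaze − head; no
  oculomotor-range saturation is modeled.
* The exact double-step target pairings of the original experiment are
  figure-only; the default configuration (T1 at ±20/±27 deg on the
  horizontal meridian × 36 T2 positions = 144 pairs) mirrors the stated
  design logic (horizontal first shifts, 144 unique pairs) but is not a
  reconstruction.
* Real-data artifacts (blinks, coil slips, curved saccades) are out of
  scope for both the simulator and the detector.
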