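---
title: "Methods: from stereo detections to mixed-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stereo detections to mixed-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flighttunnel)
```

`flighttunnel` implements a complete measurement-and-inference chain for
flight experiments in an obstacle-field tunnel: honeybees transit a
200 × 191 × 1150 mm enclosure containing three rows of five vertical
7-mm columns, leaving two 57-mm corridors, and are filmed by two
synchronized high-speed cameras at 500 frames/s.  Because raw videos of
such experiments are rarely deposited, the package pairs the measurement
chain with a synthetic generator that produces ground-truth flights and
stereo observations with known statistical structure, so every stage —
detection, tracking, triangulation, smoothing, metrics, and the mixed
models — is testable end to end.

## World frame and scene geometry

All stages share one right-handed frame: `x` longitudinal (mm), `y`
lateral with the centreline at 0, `z` altitude above the floor.  The
obstacle rows sit at `y = -64, 0, 64` so that the edge-to-edge gap between
adjacent rows is exactly the 57-mm corridor width; the resulting clearance
between the outer columns and the walls is 32.5 mm edge-to-edge.  That
wall gap follows from the corridor width and column diameter in a 200-mm
tunnel; we treat the corridor width as the authoritative dimension and let
the wall gap fall out of the arithmetic.  The field heights studied are
11, 40, 69, 98 and 127 mm; the 11-mm field is a control too short to fly
within.  The tallest field leaves 64 mm of obstruction-free space below
the ceiling.  Flights entering the *excluded zone* — within 15 mm of the
ceiling — are discarded, as in the filming protocol; the boundary itself
(`z = 176` exactly) is kept, applying the rule to the observed, unsmoothed
positions, because discard decisions in the experiment were made on
observed tracks.

Two open geometric choices are declared rather than inferred: the field
occupies the central 40 % of the tunnel length (`x` from 345 to 805 mm),
and the five columns per row are evenly spaced across that extent.
Clipping to the transit uses the **closed** interval: a sample exactly on
the field boundary belongs to the transit.

## Camera model and triangulation

Cameras are pinholes with two radial distortion terms
(`1 + k1 r^2 + k2 r^4` on normalized coordinates), the model a
checkerboard calibration yields; tangential distortion is omitted.
Undistortion inverts the radial polynomial by fixed-point iteration
(20 iterations or 1e-12, whichever first).  Two-view triangulation
back-projects the undistorted pixels to rays and takes the midpoint of the
common perpendicular (the closed-form two-ray least-squares solution),
reporting the mean reprojection error over both views; rays closer than
about 0.006 degrees to parallel are refused as degenerate.  Calibration
estimation itself is out of scope: camera parameters are inputs (JSON
files), and the synthetic rig supplies ground truth.

The default synthetic rig mimics the filming geometry — two cameras high
above the up-tunnel end on opposing sides (`±300` mm laterally, 1500 mm
up), optical axes about 28° off vertical, looking down the tunnel at the
field centre — with 3000-px focal length, 1280 × 960 sensors and mild
radial distortion (`k1 = -0.08`, `k2 = 0.01`).  With this rig, half-pixel
detection noise triangulates to a median 3D error of about 0.8 mm.

## Detection and tracking

Blob detection subtracts a per-pixel median background, thresholds the
absolute difference, extracts 8-connected components, and reports
intensity-weighted centroids (sub-pixel accuracy on Gaussian-blob
renders), largest first.  Tracking is a constant-velocity Kalman filter
on pixel position with Munkres assignment of detections to the predicted
position.  The filter uses the discrete white-noise-acceleration model;
because process and measurement noise are isotropic the two image axes
share one covariance recursion.  Defaults (declared, since no tracker
tuning is published for this experiment): acceleration noise 1 px/frame²,
measurement noise 0.7 px, a 25-px Euclidean validation gate, at most 10
coasted frames, and a 20-frame minimum track length.  Costs inside the
gate are Euclidean distances; with a single bee per trial the assignment
is usually 1-to-1, but Munkres keeps reflections and other distractors
from stealing the track.

On measured frames the recorded track position is the detection centroid
itself; the filter state drives prediction, gating and coasting only.
This keeps clean measurements untouched (a noiseless render round-trips
to machine precision) while still bridging dropouts.  The manual review
step of interactive digitising tools is replaced by an automatic repair
pass: frames whose displacement exceeds the median by more than five
median absolute deviations are treated as misses and re-interpolated.

## Reconstruction, clipping, smoothing

Frames measured in both views are triangulated; frames coasted in one
view are triangulated but flagged `coasted_one`; frames coasted in both
are dropped.  A median reprojection error above 5 px marks the flight
with a calibration warning.  After clipping and the excluded-zone rule,
each axis is smoothed with a penalized quintic (order-6) B-spline
minimizing `sum (y - f(t))^2 + lambda * int f'''(t)^2 dt` — the quintic
analogue of the cubic smoothing spline, leaving velocity and acceleration
unpenalized up to quadratic trends and giving analytic derivatives for
velocity.  The basis has roughly one knot per eight samples (capped at 40
functions); `lambda` is selected per axis by generalized cross-validation
over a 29-point logarithmic grid via the Demmler–Reinsch rotation, with a
fixed-parameter override for reproducibility.  `lambda = 0` reproduces
any quintic polynomial exactly.  Metrics are computed from the smoothed
trajectory (a declared choice; whether published analyses used raw or
smoothed altitudes is not stated — the difference is sub-millimetre
here).

## Flight metrics

Per transit: median altitude above the floor; altitudinal range
(max − min); altitude relative to the obstacle tops
(`altitude_obstacle = altitude_floor − field height`); the categorical
route, `above` iff `altitude_obstacle > 0` with the boundary assigned to
`within`; ground speed as the median horizontal-plane speed
`sqrt(vx² + vy²)` (the wind is not subtracted); lateral excursion as the
interquartile range of `y` under the type-7 quantile convention (IQR
values depend on the convention, so it is fixed and documented); the
entry-to-exit speed change using 10 % end windows (the window length is
our choice; no definition is published); and a collision flag when the
horizontal clearance to a column reaching the bee's altitude falls below
a 6-mm body radius (approximate — whether a reported collision counted
wing or body contact is unknown).  The airspeed helper returns
`ground_speed − signed wind speed`; holding the preferred 0.32 m/s ground
speed in a 0.54 m/s tailwind therefore requires flying backwards relative
to the air at 0.22 m/s.

## The synthetic generator

The generator's defaults are the study conditions: 58 bees, 5–13 flights
each (mean ≈ 9), one field height per bee chosen at random, one
contiguous still-air block and one windy block per bee (random starting
condition, since wind covaries with flight number), directions
alternating, 0.54 m/s wind.  Behavioural structure is injected
multiplicatively on medians of lognormal distributions so that ratios of
medians equal the configured ratios exactly: above-route flights 40 %
faster and 36 % wider-casting than within-route, windy excursions 19 %
larger, tailwind speeds 23 % faster than still air, headwind speeds equal
to still air (matching the observed headwind/still similarity).  Route
probabilities per field height are 0, 0.05, 0.10, 0.25, 0.55 — zero at
the control height and a majority-within tallest field; these are
qualitative choices, as exact per-height route counts are not published.

Three calibrations make the configured numbers mean what their names say,
all derived analytically at configuration time, never from data:

* the still-air median ground speed (0.32 m/s) is the median of the
  route-mixture distribution, so the above-route location parameter is
  found by inverting the lognormal-mixture CDF implied by the route
  probabilities;
* the casting amplitude is scaled by the realized IQR of a unit sinusoid
  over the flight's own in-field window (a transit covers only a few
  casting cycles, and faster flights cover fewer, so using `A√2` alone
  would bias fast groups low);
* forward speed is solved so that the median horizontal speed *including*
  the casting velocity equals the flight's target ground speed.

Altitude follows a random-phase sinusoid around the route-appropriate
level plus a small Ornstein–Uhlenbeck-style jitter, with the amplitude
drawn so the per-transit max − min has median 20.9 mm.  A bounded
oscillation is used rather than a free mean-reverting walk because the
configured quantity is the median range, which a sinusoid delivers in
closed form (twice the amplitude) while a random walk's range
distribution would itself need numerical calibration.  Above-route levels
sit near the 100-mm preference (shifted up 22.2 / 26.6 mm at the 98- and
127-mm fields, and always at least 12 mm above the obstacle tops);
within-route flights centre vertically in the field and laterally in a
randomly chosen corridor.  Casting frequencies are 1.4 Hz lateral and
1.7 Hz vertical — the order observed for honeybee casting, chosen once;
the metrics depend only on positional statistics, not on the control law,
which is why no optic-flow controller is simulated.  Per-bee lognormal
speed intercepts (sd 0.10) and altitude intercepts (sd 6 mm), per-flight
speed sd 0.12, excursion sd 0.15 and range sd 0.25 are realistic
dispersions for individual honeybees; high-frequency positional jitter
(0.8 mm lateral, 0.3 mm vertical) stands in for wingbeat-scale motion and
is what the smoother is expected to remove, so ground-truth metrics are
defined on the smooth component.

Observation projects each sample into both cameras, keeps in-frame
points, adds isotropic pixel noise (default 0.5 px), drops detections
independently (default 2 %), and can inject distractors.  A small frame
renderer (speckled static background plus a moving Gaussian blob)
exercises the blob detector at fixture scale.

What the generator does **not** emulate: aerodynamics and wake effects of
the columns, visual guidance and optic-flow control, wing kinematics,
appearance variation, rolling shutter, or calibration error.  Passing
tests therefore demonstrate that the measurement chain recovers the
statistical structure present in idealized observations of plausible
trajectories — not that it would survive miscalibrated cameras or
appearance-driven detection failures on real footage.

## The inference layer

Models are fitted with `nlme::lme` — the tool this experimental
literature itself uses — behind the package's `fit_lmm` surface: a bee
random intercept, REML by default, and optionally one residual scale per
stratum (`varIdent`).  Responses are transformed first: squared median
altitude, log10 range, log10 ground speed, cube-root lateral excursion.
Homogeneity is checked with classic Levene tests (mean centring by
default, median optional; the centring convention is not published).

Variance-structure selection refits the altitude model with all seven
non-empty subsets of {wind, direction, field height} as strata plus the
homoskedastic base — all REML with identical fixed effects, ranked by
AIC.  Altitude-definition selection compares three candidates for the
performance metrics: altitude-above-floor with field height, altitude
relative to the obstacle tops, and the categorical route, each with wind
and direction interactions.  Because these differ in fixed effects, the
ranking uses maximum-likelihood refits (REML likelihoods are not
comparable across fixed-effect structures); REML AICs are reported
alongside.  The AIC parameter count is the fitted object's: fixed
effects plus variance parameters.  Marginal means and Tukey-adjusted
pairwise contrasts come from `emmeans` with containment degrees of
freedom, matching the F/t reporting style of `lme`-based analyses.
First-vs-last paired t-tests (per wind stratum, because wind covaries
with flight number) check for session-long drift before flights are
treated as exchangeable.  Significance is assessed at 0.05 throughout.

## Numerical choices and degenerate inputs

Strictly increasing times are required for smoothing; fewer than 12
samples is an error.  Tracks need 20 overlapping frames to reconstruct.
Near-parallel rays, empty cost matrices, single-group Levene calls,
non-positive values under log10 (reported with the offending flight id),
and unknown configuration keys all fail fast with named errors.
Non-converged mixed models are returned flagged with the optimizer
message, and candidate rankings proceed over the fits that converged.
The Kalman covariance recursion is run in scalar form (three numbers),
which is exact for the isotropic model and keeps the per-frame cost low
enough to track full experiments in pure R.

## Problem sizes used by the tests

The test-suite simulations use the full default experiment (58 bees,
~520 flights) where the claim is about the experiment-level estimator,
and 6–12-bee experiments (50–110 flights) for per-flight fidelity
checks; model-selection recovery uses 50 replicate experiments at the
metrics level.  These sizes give Monte-Carlo error comfortably inside the
asserted tolerances while keeping the suite quick to run.

## Known limitations

Single-target tracking only; identity maintenance across multiple animals
is out of scope.  The collision metric is geometric and approximate.  The
generator's casting is a sinusoid, so spectral analyses of real casting
would not be meaningfully testable against it.  Calibration is assumed
known; reprojection-error flags detect gross mismatch but no bundle
adjustment is provided.
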