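---
title: "Measuring robot-induced flock redistribution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring robot-induced flock redistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockzone)
```

`flockzone` turns per-frame object-detection tables from a broiler-house
camera into a quantitative account of how a patrolling ground robot
displaces birds and how quickly they come back. This vignette is the
package's own description of the underlying models, the parameters that
matter, and the choices made where the method left room.

## The measurement model

**Input.** One CSV row per detected object and second:
`video_id, time_s, class, x_min, y_min, width, height, confidence`, with
class one of `chicken`, `robot`, `feeder` and confidence on the 0–100
scale. Boxes are axis-aligned pixels, origin top-left, half-open on the
right/bottom edges; centroids are box centres. Feeders are read and carried
through but play no role downstream. The reader accepts any strictly
increasing set of integer sample times: recordings with dropped seconds
remain analysable, and every downstream window rule tolerates gaps.

**Trajectory and zone.** The robot's per-frame centroids, in time order,
form the trajectory polyline (frames with several robot boxes keep the
highest-confidence one; ties go to the larger box, then first occurrence).
Gaps are linearly interpolated at 1-s resolution for bookkeeping only —
interpolated points never enter the polyline, so a dropped frame cannot
bend the path. The zone of influence is the set of points within
`factor × w` of the polyline, with `factor = 1.5` and `w` the apparent
robot width: the median over robot detections of `min(width, height)`. The
physical robot is 38 × 31 cm, so its smaller box side tracks the true
31-cm width whatever the robot's orientation in the image; the median
resists occasional bad boxes. Membership is boundary-inclusive
(`distance ≤ half_width`), which keeps zone membership monotone in
`factor` (closed sets nest). Endpoints get round caps — the zone extends
one half-width beyond the first and last observed centroid; an option
extends the polyline to the frame edges along its end-segment directions
when the robot's path visibly spans the whole field. The raw polyline is
used rather than a fitted straight line: it is assumption-free, and for a
robot on a straight transect the two coincide anyway.

**Relative density.** In-zone chicken counts `N(t)` are normalized to
`D(t) = 100 · N(t) / N̄`, with the baseline `N̄` the mean count over
`[-60, -15]` s (inclusive) relative to `t = 0`. `t = 0` is the robot's
*first detection* in the frame: of the candidate events (first detection,
first entry into the zone span) it is the only one that is unambiguous in
every video, and all windows are anchored to it. At least 10 of the 46
possible baseline seconds must be present — enough to bound the standard
error of `N̄` while tolerating camera dropouts; a zero baseline is an
explicit error, since relative density is then undefined. By construction
the mean of `D` over the complete baseline window is exactly 100%.

**Summary points.** Each video is summarised by the *moment prior* — the
maximum of `D` over `[-15, 0)`, a maximum because the pre-entry pile-up of
birds pushed ahead of the robot is brief and easily averaged away — and
the values at `t = +60` and `+120` s. The moment-prior window is half-open
so the entry frame itself is excluded. When the exact +60/+120 sample is
missing, the nearest sample within 2 s substitutes and the result is
flagged (ties go to the earlier sample); beyond 2 s the window counts as
uncovered and the summary errors rather than guessing.

**Repopulation.** After the robot's passage, `D(t)` is modelled as a
straight line fitted by ordinary least squares over a window that starts,
by default, at the robot's *exit* (last detection) — "after the passage" —
and ends at +240 s or the end of the series. The slope is in percent per
second; the intercept is the level at the window start; `R²` is reported,
defined as 0 for a zero-variance response rather than `NaN` so that a
perfectly empty zone yields a usable "no repopulation" fit. Full
repopulation is the extrapolated time at which the line reaches 100%:
`t_start + (100 − a)/b`. A slope below `1e-6` %/s is treated as no
repopulation (`NA`), and an intercept already at 100% gives 0. Group-level
estimates average replicate series pointwise on the relative clock first
and fit the mean curve (`fit_mean_curve()`), which weights each second
equally rather than each sample; single-series fits remain available.

**Detector evaluation.** Predictions at or above confidence 50 are matched
greedily per frame and class, in descending confidence order, to the
unmatched ground-truth box of highest IoU, accepting IoU ≥ 0.3 — the
de-facto standard matcher in detection evaluation. Counts are pooled
(micro-averaged) over frames. Precision, recall and F1 are on the percent
scale with 0/0 defined as 0 (warned) so empty fixtures stay testable. AP
integrates the full confidence-ranked precision–recall curve with
all-point interpolation (the monotone precision envelope); an 11-point
option exists for comparability. mAP averages AP over the classes that
have ground truth; classes without any are excluded with a warning rather
than contributing a meaningless 0. Boxes are axis-aligned throughout.

**Ethogram statistics.** Occurrence of a behavior group is the fraction of
videos in which any behavior of the group was flagged. Testing whether
occurrence "differs from zero" is degenerate — a single success refutes
p = 0 with certainty — so the test is an exact one-sided binomial test
against a small non-zero null (default p₀ = 0.01), preserving the intent
(occurrence is non-negligible) without inventing a different statistic.
Rank transforms use ascending mid-ranks. Mixed-model fitting itself
(gamma-family for the moment prior, normal-on-ranks for the later points)
is deliberately out of scope: `density_long_table()` exports the tidy
`video_id, week, treatment, batch, timepoint, value, rank` table that any
standard GLMM tool consumes.

## The synthetic flock

No public dataset accompanies the measurement problem, so the package
ships a generator whose output has the statistical structure the analysis
assumes, making every stage testable end to end.

Birds live in a 2-D arena (default 8 × 4.5 m, rendered at 160 px/m to a
1280 × 720 frame). Each bird has a *home* drawn around one of several
cluster centres — broilers stay near conspecifics — and undisturbed birds
follow a home-anchored random walk (an Ornstein–Uhlenbeck-like process:
per-√s step SD `random_walk_sigma_m`, pull rate `cohesion_rate`),
initialized at its stationary spread so a control run has no transient.
The robot crosses a straight transect between the feed and water lines at
0.2 m/s, starting its approach 60 s before reaching the transect so a
pre-entry baseline exists; it is "detected" only while its box lies fully
inside the frame. Any bird within `flee_radius_m` of the robot moves
radially away at `flee_speed_mps` until beyond the radius plus a margin —
the minimal mechanism that clears the transect laterally and also
reproduces the brief pre-entry pile-up ahead of the robot. Once the robot
has moved on and `return_latency_s` has elapsed, a displaced bird drifts
back toward its pre-displacement home at `return_drift_mps`; zero drift
means repopulation happens only by diffusion. Integration uses a 0.1-s
internal step so flee and return speeds are not aliased at the robot's
speed; positions are recorded each second.

Rendering maps positions affinely to pixels (fixed overhead view, no
perspective — oblique-camera geometry is irrelevant to the pipeline
contract, which is in pixels) with per-bird box sizes fixed for the video.
Detection noise is optional and separately seeded per channel (misses,
false positives, jitter), so toggling noise never changes the movement
realization; with all noise off the noisy and truth series are identical
objects. Misses drop bird detections Bernoulli-wise; false positives add
Poisson-many bird-sized boxes per frame at uniform positions; jitter
perturbs box corners with Gaussian pixel noise. The simulator computes its
own ground-truth in-zone counts from the true positions and the configured
zone, giving the pipeline an exactness target: with zero noise, pipeline
counts must equal truth counts at every second.

**Presets.** Age is encoded purely through parameters — there is no growth
model. `wk1`: 60 small quasi-static birds (walk SD 0.02 m/√s) that flee
deeply (radius 1.3 m at 0.7 m/s) and do not drift back, so the zone stays
empty; `wk2`: 100 birds, radius 1.0 m, slow return (0.005 m/s after 25 s);
`wk6`: 150 large birds, shallow flight (0.55 m at 0.5 m/s) and the fastest
return (0.012 m/s after 20 s); `control`: the same flock with no robot.
These values were chosen once, as plausible magnitudes for the behavioural
contrast they encode — older, habituated birds yield less ground and
return sooner. The presets target only the *qualitative* age ordering
(younger birds depopulate more and repopulate slower); they are not
calibrated to any measured flock, and tests assert orderings and
calibration identities, never specific field values. What passing tests
show is that the estimators recover what the generator put in; they cannot
certify behaviour on real video, where detector biases are not
Bernoulli-uniform and bird motion is richer than flee-and-drift.

## Numerical and degenerate-input conventions

* Window ends: baseline `[-60, -15]` inclusive; moment prior `[-15, 0)`;
  fit window inclusive.
* Zone membership: `≤` on the boundary; membership checked by exact
  point-to-segment projection, no rasterization.
* OLS via `lm()`, with `R² = 1 − SSE/SST` computed directly and defined as
  0 when `SST = 0`.
* Matching ties (equal confidence) break by larger box area, then input
  order, making results independent of row shuffling.
* Errors are classed conditions (`flockzone_schema_error`,
  `flockzone_baseline_error`, ...) naming the offending column, row or
  window, so pipeline failures localize.
* Determinism: one seed fixes a simulation bit-for-bit; analysis stages
  are seed-free.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
300-s simulations with 60–150 birds, 200-replicate slope-recovery studies,
100 paired seeds for the age-contrast orderings, and ~2,500 ground-truth
boxes for metric calibration — sizes at which the statistical assertions
(3-SEM bands, binomial 99% bounds, 5% relative error on recovered slopes)
are well powered while a full run stays within a few minutes on one CPU.

## Known limitations

* Counting is per-frame; no identity tracking, so "repopulation" does not
  distinguish returning birds from new arrivals (nor does the field
  method).
* The linear repopulation model is only sensible on the few-minute window;
  it saturates in reality, and extrapolated full-repopulation times
  inherit that optimism.
* Pixel space throughout: no camera calibration, so zones from different
  cameras are not metrically comparable.
* The simulator's flee/return dynamics are deliberately minimal; it makes
  no claim to gait realism, habituation across days, or litter/thermal
  effects.
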