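# flockzone

Quantify how an autonomous ground robot redistributes broiler chickens,
starting from per-frame object-detection tables (one row per detected
chicken/robot/feeder bounding box, sampled at 1-s intervals from a fixed
camera).

Robots that patrol broiler houses to collect husbandry data also push birds
off their resting spots as a side effect, which is of welfare interest:
extra locomotion benefits the birds' skeletal health. `flockzone` measures
that effect. Given a video's detections it:

1. reconstructs the robot **trajectory** from its detected centroids;
2. buffers the trajectory into a **zone of influence** — all points within
   1.5 robot-widths of the path (the half-width is `1.5 × w`, with `w` the
   apparent robot width in pixels, the median of `min(box width, box
   height)` over robot detections);
3. counts the chickens whose centroids fall in the zone each second and
   normalizes the counts to a **relative density**
   `D(t) = 100 · N(t) / N̄_base`, where `N̄_base` is the mean count over the
   window 60–15 s before the robot is first detected;
4. summarises each video by the **moment prior** (max of `D` over
   `[-15, 0)` s), and `D` at **+60 s** and **+120 s**;
5. fits the **repopulation model** `D(t) = a + b·(t − t_start)` by ordinary
   least squares after the robot's passage and extrapolates the full
   repopulation time `t_start + (100 − a)/b`.

It also implements detection-performance evaluation (IoU matching at
threshold 0.3 and confidence 50; precision, recall,
`F1 = 2PR/(P + R)`, per-class AP and mAP), ethogram statistics
(occurrence-proportion tests, rank transforms, birds-touched summaries),
and an agent-based **synthetic flock simulator** — clustered birds with a
home-anchored random walk, a robot on a straight transect at 0.2 m/s,
flee-on-approach and drift-back dynamics, and injectable detection noise —
so every pipeline stage is testable without farm video.

## Worked example

Simulate a late-cycle (week-6-like) flock and run the full pipeline:

```r
library(flockzone)

sim    <- simulate_flock(scenario_preset("wk6", seed = 3))
report <- run_pipeline(sim$detections)

report$baseline$baseline_count
#> [1] 33.30435
report$summary$minute_after_pct
#> [1] 81.08225
report$fit
#> <repopulation_fit> slope 0.2548 %/s, intercept 66.0 %, R^2 0.570 (n = 202, window [38, 239] s)
report$full_repopulation_time_s
#> [1] 171.5483
```

Read: the zone held ~33 birds on average before the robot appeared; one
minute after entry the zone is back to 81% of baseline; after the robot's
passage density recovers at 0.25 percentage points per second, reaching the
baseline level ~172 s after entry. A `wk1` preset (small birds that flee
far and do not drift back) instead gives a minute-after density near 0 and
a slope near 0 — no repopulation on the observed timescale.

For a control recording there is no robot to define the zone or the clock,
so both are imported:

```r
ctl <- simulate_flock(scenario_preset("control", seed = 3))
rep <- run_pipeline(ctl$detections, zone = ctl$zone, t0_s = ctl$nominal_entry_s)
mean(rep$density$relative_density_pct)
#> [1] 95.77419
```

Detector evaluation uses the same table schema (ground truth at
confidence 100). On a noise-free simulation it is trivially perfect; with
injected noise (`detect_miss_rate`, `false_positive_rate`,
`box_jitter_px`) it recovers the injected rates:

```r
m <- evaluate_detections(sim$detections, sim$truth_detections)
c(m$precision, m$recall, m$f1, m$mean_ap)
#> [1] 100 100 100 100
```

See the vignette (`vignettes/flock-density-dynamics.Rmd`) for the model
details, the simulator's assumptions, and every tunable parameter.

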