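# gloveforge

Simulation-driven design of sensor-instrumented gloves for gesture
recognition.

Building a smart glove normally means guessing sensor positions, wiring a
prototype, collecting data, and discovering too late that half the IMUs are
redundant. gloveforge inverts that loop: starting from hand motion alone —
motion-capture key-points, monocular-video key-point estimates, or fully
synthetic gestures — it simulates the glove end to end and reports which
sensor placements are worth building. It is written for wearable-sensing and
movement-biomechanics researchers who want to compare glove designs at a
desk, before any hardware exists.

The pipeline:

1. **Preprocessing** — noisy 21-key-point trajectories are mirrored to a
   right hand, each bone rescaled to the model's length per frame (monocular
   estimators drift), translated to the wrist and rotated onto the model by
   the Kabsch algorithm.
2. **Inverse kinematics** — a 26-DOF kinematic right hand (6-DOF wrist +
   4 DOF per finger) is fitted per frame by constrained least squares,
   producing joint-angle motion files plus quality diagnostics: mean
   distance error (MDE, mm), constraint violation ratio (CVR, %) and
   magnitude (CVM, degrees). Poor takes are filtered by MDE threshold or
   best-k per gesture.
3. **Augmentation** — hand sizes are resampled from anthropometric
   distributions (length ~ N(19.3 cm, 1.25 cm), index:ring ratio
   ~ N(1.0, 0.05)); gesture style is varied by key-pose time warping: key
   poses are extrema of the variance trace `D = sqrt(Tr(Q Qᵀ))` of the
   windowed joint-angle covariance, inter-pose durations are multiplied by
   `1 + u`, `u ~ U(−0.4, 0.4)`, and segments are Fourier-resampled and
   Butterworth-smoothed.
4. **IMU synthesis** — for each of 15 candidate phalanx sites, accelerometer
   (`a = d²p/dt²`, reported as specific force including gravity), gyroscope
   (`ω = 2 q* dq/dt`, cross-checked against `S(ω) = (dR/dt) Rᵀ`) and
   magnetometer readings, through a parametric error model (range,
   resolution, bias, misalignment, noise density, bias instability, random
   walk).
5. **Placement scoring** — Pearson-correlation-based independence scores:
   inter-joint independence `G = 1 − |mean r|`, finger redundancy
   `D_fa = max_{f'} |mean r|`, inter-finger independence
   `H_f = 1 − min_a D_fa`, combined into a per-site importance `I` and a
   ranking of all 15 sites with nested best-k / worst-k candidate sets.
6. **Design evaluation** — 0.5 s sliding windows (80% overlap), leakage-safe
   0.6/0.2/0.2 take-level splits, training-time rotation and multiplicative
   noise augmentation, pluggable classifiers, and a report of support-
   weighted F1 (`F1 = 2TP/(2TP+FP+FN)`) per candidate sensor set.

A synthetic gesture generator (`gesture_vocabulary()`, `pinch_vocabulary()`,
`build_benchmark()`) makes the whole pipeline runnable and testable with no
external datasets.

## Worked example

Rank sensor sites on a synthetic three-gesture benchmark and compare the
best three sites against the worst three:

```r
library(gloveforge)
set.seed(11)

bench <- build_benchmark(pinch_vocabulary(), n_subjects = 2,
                         takes_per_gesture = 6, rate = 30, duration = 2)
scores <- importance_scores(bench$dataset)
print(scores)
```

```
<placement_scores> site ranking (most important first):
   1. thumb_distal       I = 1.0000
   2. index_distal       I = 1.0000
   3. thumb_proximal     I = 0.8836
   4. index_middle       I = 0.8783
   5. thumb_metacarpal   I = 0.8138
   6. index_proximal     I = 0.7772
   7. pinky_distal       I = 0.2586
   8. middle_distal      I = 0.2582
   9. ring_distal        I = 0.2582
  10. middle_middle      I = 0.0025
  ...
  15. pinky_proximal     I = 0.0000
```

In this vocabulary the middle, ring and pinky fingers curl identically in
every gesture, so they are mutually redundant (importance ≈ 0), while the
thumb and index carry all class information — the ranking recovers exactly
that. An importance of 1 means the site's finger is fully independent of the
others in at least one gesture; 0 means another finger predicts it
everywhere.

```r
sets <- candidate_sets(scores, 3)
sites <- unique(c(sets$best[[3]], sets$worst[[3]]))
streams <- simulate_sensor_streams(bench$dataset$takes, bench$models, sites)
windows <- sliding_windows(streams, window_s = 0.5, overlap = 0.8)
ids  <- vapply(streams, `[[`, character(1), "take_id")
acts <- vapply(streams, `[[`, character(1), "activity")
split <- split_takes(ids, acts, seed = 1)
windows <- normalize_windows(windows, split)
report <- design_report(windows, split,
                        list(best = list(sets$best[[3]]),
                             worst = list(sets$worst[[3]])), seed = 1)
print(report[, c("config", "n_sensors", "sites", "weighted_f1")])
```

```
  config n_sensors                                        sites weighted_f1
1   best         3     thumb_distal+index_distal+thumb_proximal    1.000000
2  worst         3 pinky_proximal+middle_proximal+ring_proximal    0.629994
```

Three well-placed sensors classify the vocabulary perfectly; the three
lowest-ranked sites, which see only motion common to all gestures, reach a
weighted F1 of 0.63 — residual accuracy coming mostly from gravity/
orientation cues in the accelerometer channels.

A thin command-line front end wraps the same functions:

```sh
exec/gloveforge synth --out takes/ --vocabulary pinch --seed 1
exec/gloveforge rank  --motions takes/ --manifest takes/manifest.csv --out placement.json
exec/gloveforge ik    --markers markers.csv --out motion.csv
exec/gloveforge simulate --motion motion.csv --site index_distal --out imu.csv
```

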