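---
title: "Methods: simulation-driven smart-glove design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-driven smart-glove design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gloveforge)
```

gloveforge turns recorded (or synthesized) hand motion into a ranked smart-glove
design: which of 15 candidate phalanx-mounted IMUs to keep, and what gesture
recognition performance to expect from each candidate set, all before any
hardware is built. This vignette documents the models, the tunable parameters,
and the design choices behind each stage.

## The kinematic hand model

The hand is a pure kinematic chain with 26 degrees of freedom: a free wrist
(3 translations in meters plus 3 rotations) and five fingers with 4 DOF each.
Non-thumb fingers articulate at the metacarpophalangeal joint (flexion and
abduction) and have hinge PIP and DIP joints; the thumb articulates at the
carpometacarpal joint (flexion and abduction) with hinge MCP and IP joints.
There is no muscle, tendon, contact or dynamic modeling: inverse kinematics
and sensor synthesis only need the geometry.

The wrist frame is x-radial (towards the thumb), y-distal, z-dorsal. The 21
markers follow the standard hand key-point numbering: marker 0 on the wrist,
then four markers per finger from base joint to fingertip (thumb first). The
15 candidate sensor sites sit at phalanx midpoints — distal, middle and
proximal phalanx per non-thumb finger; distal and proximal phalanx plus the
metacarpal for the thumb — and inherit the local segment frame.

Default geometry is expressed as fractions of the hand length (wrist to
middle fingertip), whose default 0.193 m is the adult population mean; the
palm spans 0.55 of the hand length and the per-finger segment fractions
follow anthropometric proportions, with index and ring fingers equal at rest
so the base index:ring ratio is exactly 1. Joint limits are data, not code:
the default table (MCP flexion −20°…90°, PIP 0°…110°, DIP −10°…90°,
abduction ±25°, thumb CMC −30°…60° / −10°…60°, thumb MCP 0°…60°, IP
−10°…80°) is shipped in the model object, serializes to YAML with
`write_hand_model()`, and can be replaced wholesale by users with better
anthropometric sources. The limit values themselves are documented stand-ins
chosen from common clinical ranges of motion.

Quaternions are scalar-first with the Hamilton product. Throughout the
package a quaternion attached to a body (wrist or sensor) is an *attitude*:
it rotates body-frame vectors into the ground frame. Its conjugate maps
ground-frame vectors into the sensor frame; `sensor_frame_kinematics()`
documents this explicitly, and the angular-velocity cross-check below pins
the convention.

## Preprocessing

Raw key-point sequences — motion-capture exports or monocular video
estimates — arrive in arbitrary units, arbitrary (and possibly per-frame
drifting) coordinate frames, and either chirality. Preprocessing applies, in
order:

1. **Mirroring** (left hands only): x-negation about the sagittal plane
   through the wrist marker. When handedness metadata is missing,
   `detect_handedness()` uses the signed volume of the tetrahedron (wrist,
   thumb CMC, index MCP, pinky MCP). The thumb base is the one marker
   reliably out of the palm plane, so this volume is non-degenerate even for
   a perfectly flat hand — a coplanar alternative (e.g. using the middle
   fingertip) has zero volume at rest and an unreliable sign.
2. **Per-segment scaling**: every one of the 20 hand segments is rescaled to
   its model rest length, walking outward from the wrist so the chain stays
   connected; directions are preserved and per-frame bone-length drift from
   monocular estimators is removed. A zero-length observed segment reuses
   the previous frame's direction.
3. **Wrist translation**: every frame is shifted so marker 0 coincides with
   the model wrist.
4. **Kabsch rotation**: per frame, the proper rotation minimizing the
   summed squared distance to the model's rest markers (SVD of the
   cross-covariance with the standard reflection fix). Because translation
   has just been pinned at the wrist, the rotation used by
   `preprocess_sequence()` is computed about the wrist (uncentered
   cross-covariance) — rotating about the centroid would un-pin the wrist.
   The exported `kabsch_rotation()` centers by default, which is the
   textbook contract for standalone use.

The Kabsch correspondence set defaults to all 21 markers, computed per frame
(the source frame can drift per time step). With all 21 markers a flexed
pose is slightly re-aligned towards the rest pose — by design, since the
wrist orientation is re-estimated by IK afterwards. When exact
reproduction of model-compatible input matters (round-trip validation), the
`kabsch_markers = palm_marker_indices()` option anchors the alignment on the
six rigid palm markers, which finger motion cannot perturb. The whole
pipeline is idempotent and equivariant under similarity transforms of its
input; both properties are exercised in the test suite.

## Inverse kinematics

Per frame, IK finds joint angles minimizing the mean squared marker error,
with joint limits enforced as *soft* quadratic penalties — violations are
discouraged, not forbidden, and surviving violations are reported rather
than hidden. The solver exploits the kinematic tree instead of solving all
26 DOF jointly:

- the wrist frame has a closed-form optimum: a Kabsch fit over the six rigid
  palm markers (wrist, thumb CMC, four non-thumb MCPs), which finger motion
  cannot move;
- each finger's 4 DOF are then solved independently by Levenberg–Marquardt
  least squares (`minpack.lm::nls.lm`) on its three moving markers
  (9 residuals), with penalty residuals `sqrt(w) * degrees-past-limit`.

The default penalty weight `1e-6` makes one degree of violation cost as much
as one millimeter of marker error; weight 0 disables constraints entirely
(useful to *measure* how much the input data violates the limits). The
Jacobian is a forward difference with a fixed absolute step of 1e-6 degrees:
a step relative to the parameter magnitude — the default of most solvers —
collapses to nothing for a joint sitting numerically at zero and silently
freezes it, which is precisely the warm-start state of a still joint. If the
first fit leaves more than ~1 mm RMS residual the finger is re-solved from a
mid-range start and the better optimum kept; the frame solution is never
returned if it fits worse than its initialization. Sequences are solved with
warm starts by default (`ik_config(warm_start = TRUE)`, iteration cap 200,
tolerance 1e-8).

Diagnostics mirror standard IK quality reporting: the mean distance error
MDE (mm, averaged over all 21 markers and frames), the constraint violation
ratio CVR (% of frame–joint pairs outside the limits, always computed on the
*unclipped* solution) and the violation magnitude CVM (mean/sd degrees past
the limit among violations). `clip_to_limits()` afterwards forces angles
into range (idempotently), and `filter_takes()` implements both filtering
styles used in practice: a hard MDE threshold (default 10 mm — noiseless
synthetic recovery sits well below 1 mm and heavily corrupted monocular
takes above 10 mm, so the default separates the regimes; it is configurable)
and keeping the best k takes per gesture.

## Augmentation

**Hand-size augmentation** draws hand length ~ Normal(19.3 cm, 1.25 cm) and
index:ring length ratio ~ Normal(1.0, 0.05), truncated at ±4 sd to exclude
non-physical hands. Because joint angles are size-free, a variant is the
*unchanged* motion paired with a rescaled model; the variation emerges
downstream in the simulated sensor trajectories. The rescaling is exact: the
wrist-to-middle-fingertip distance matches the draw to 1e-9 m, and the
index/ring phalanges are counter-scaled by the square root of the ratio so
their combined size is preserved.

**Gesture-style augmentation** warps time between key poses:

1. The variance trace `D = sqrt(Tr(Q Q^T))` is computed per sliding analysis
   window, where `Q` holds the eigenvectors of the windowed joint-angle
   covariance scaled by the square roots of their eigenvalues — algebraically
   the square root of the total windowed variance, but computed through the
   eigendecomposition it is defined by. The windowed covariance over
   joint-angle channels is the reading that makes `D` vary along the take
   and expresses "how much the motion as a whole is changing here"; the
   default window is 5 frames (~0.17 s at 30 Hz).
2. Key poses are the prominence-qualified local minima and maxima of the
   normalized `D` (prominence threshold 0.1 of the normalized range by
   default), plus always the first and last frame.
3. Each inter-key-pose duration is multiplied by `1 + u`,
   `u ~ Uniform(−0.4, 0.4)`. The multiplier form `(1 + u)` is chosen so that
   `u = 0` means "no change"; uniform is the maximal-entropy choice for a
   stated bound. Segments are resampled to their new lengths by the Fourier
   method (FFT spectrum truncation/padding — validated against an
   independent reference implementation to machine precision), low-pass
   filtered with a Butterworth filter (order 4, cutoff 0.3 of Nyquist) to
   suppress resampling end effects, and re-joined with pinned endpoints.

Numerical care in step 3: each segment is detrended through its endpoints
before the FFT (the residual vanishes at both ends, so the periodic
extension has no jump), the filter runs on odd-reflection-padded data to
avoid edge transients, and endpoints are re-pinned afterwards. The net
guarantees, asserted as properties in the test suite: key-pose angles are
preserved within 2° per joint, warped amplitudes never exceed the source
range by more than 2°, and no instantaneous jumps appear at segment joins.
Recommended augmentation proportions are 5–10% of the original data;
augmented takes carry provenance (`$meta`: source take, drawn `u`, kind) that
the split logic consumes.

## IMU synthesis

Ground frame: z-up, gravity (0, 0, −9.80665) m/s². For a sensor site the
pose trajectory p(t), q(t) from forward kinematics is resampled to the IMU
rate (default 100 Hz; cubic splines for position, hemisphere-aligned slerp
for orientation), then differentiated numerically (central differences,
second-order one-sided at the ends):

- linear acceleration `a = d²p/dt²` (ground frame);
- angular velocity `ω = 2 q* (dq/dt)` — with attitude quaternions this is
  the body-frame (sensor-frame) rate, exactly what a gyroscope reads;
- independently, `S(ω) = (dR/dt) Rᵀ` extracts the ground-frame rate from the
  rotation-matrix trajectory; the two paths agree to 1e-6 rad/s on smooth
  slow trajectories at 100 Hz (truncation errors differ at
  O(ω³ dt²), so the agreement is checked where both use central
  differences), which pins the frame conventions against each other.

The accelerometer reads specific force `q*(a − g)q`: at rest, (0, 0, +g);
in free fall, zero; under tilt, the gravity decomposition across axes —
which is how orientation leaks usefully into accelerometer features. The
magnetometer reads a constant ground field (default (19, 0, −45) µT,
magnitude ≈ 49 µT) rotated into the sensor frame, so its magnitude is
time-invariant by construction.

The error model applies, per modality:
`y = quantize(saturate(M diag(s) x + bias + white + bias_instability + walk))`
with white-noise sd `noise_density · sqrt(rate/2)`, bias instability as
first-order low-pass-filtered white noise, and random walk as integrated
white noise. Defaults are wearable-grade datasheet values for resolution and
noise density with the remaining stochastic terms zero; every term has a
neutral value, and the model with all-neutral parameters is bit-identical to
the identity.

## Sensor placement scoring

Given a labeled dataset of joint-angle takes `x[a, s, f, j]` (activity a,
session s, finger f, joint j), the scores are built from Pearson
correlations, with the convention that a constant series (no movement)
correlates 0 with everything — stillness is uninformative, not undefined:

- **Inter-joint independence** `G = 1 − | mean_a mean_s r(x_j1, x_j2) |`,
  sessions averaged within each activity, activities weighted equally so
  dataset imbalance cannot bias the score. The absolute value wraps the
  *averaged signed* correlation, as the formula is printed in its source —
  opposite-signed correlations across activities can therefore cancel and
  raise G. We implement it as printed and note the alternative
  (mean-of-|r|) would be strictly more conservative.
- **Finger redundancy** `D[f, a]`: for each other finger, the correlation of
  role-paired joints (thumb pairing: CMC flexion↔MCP flexion, CMC
  abduction↔abduction, MCP↔PIP, IP↔DIP; J = 4) averaged over joints and
  sessions, absolute value taken, then the maximum over other fingers.
  Because the joint average sits *inside* the absolute value, negating one
  joint column can legitimately change D; negating a whole finger cannot —
  the property tests assert exactly that.
- **Inter-finger independence** `H_f = 1 − min_a D[f, a]`: a finger is
  independent if there is at least one activity in which no other finger
  predicts it.
- **Site importance**: distal sites score `H_f` (fingertips see the widest
  motion); middle sites `G(DIP, PIP) · H_f`; proximal sites
  `G(PIP, MCP) · G(DIP, MCP) · H_f`; thumb: distal `H`, proximal
  `G(IP, MCP) · H`, metacarpal `G(IP, CMC) · G(MCP, CMC) · H`.

Sites are ranked by descending importance with a deterministic anatomical
tie-break (thumb→pinky, distal→proximal); an all-zero ranking is flagged
degenerate rather than presented as meaningful. `candidate_sets()` emits the
nested best-i sets plus complementary worst-i sets for best-versus-worst
design comparisons. The entire scoring path is verified against an
independent nested-loop evaluation to 1e-12 on random datasets.

## Classification pipeline

Simulated streams are segmented into 0.5 s sliding windows with 80% overlap
(stride = window · (1 − overlap)), each labeled by the majority activity
within it. Splits (0.6/0.2/0.2 train/validation/test) are made at the take
level, stratified by gesture, on *source* takes only; every augmented take
inherits its source's split, so no augmented echo of a test gesture can
reach training. Normalization to zero mean and unit variance uses training
statistics only (zero-variance channels are mean-centered).

Training-time augmentation mirrors deployment variability: one uniformly
random 3D rotation per window applied jointly to each sensor's
accelerometer/gyroscope/magnetometer triplets (unknown mounting
orientation), then element-wise multiplicative Gaussian noise with mean 1
and sd 0.2.

Classifiers are pluggable via a two-function contract (`fit(windows,
labels)`, `predict(model, windows)`). The reference implementation feeds
five order-free summary features per channel (mean, sd, min, max, RMS of the
first difference) to a random forest — fast enough for continuous testing
and strong enough to expose the information gap between good and bad sensor
sets; a convolutional sequence model can be substituted without touching the
pipeline. Evaluation uses per-class `F1 = 2TP / (2TP + FP + FN)` weighted by
class support; `design_report()` tabulates weighted F1 per candidate set
together with hardware-independent cost proxies (channel and feature
counts). On-device profiling is an extension point, not a dependency.

## The synthetic gesture generator

`gesture_template()` defines a gesture as key poses (time fraction + sparse
angle map) connected by smoothstep interpolation, with per-take jitter on
key-pose angles (clipped to the joint limits, so in-limits templates always
yield in-limits takes — smoothstep is monotone between endpoints) and on
duration. `project_to_markers()` forward-projects a motion to markers with
isotropic Gaussian noise and optional per-frame scale drift and rigid
jitter, emulating exactly the corruption modes preprocessing removes.
`build_benchmark()` samples per-subject hand dimensions and builds labeled
multi-subject datasets.

Two vocabularies ship with the package. The case-study-style set
(thumbs-up, fist, rocker, spread) uses documented fixture angles. The
*pinch* construction is an engineered ground truth for placement: middle,
ring and pinky curl identically in every gesture (cross-finger correlation
≈ 1, hence H ≈ 0), while thumb and index are the only discriminative
actors — and each is still in one gesture, which drives its best-case
redundancy to the r = 0 convention and its H to 1. Every top-ranked site
must therefore lie on the thumb or index, and a classifier restricted to
the three worst sites has almost nothing to learn from. This is what the
placement and end-to-end tests check.

What the generator does *not* emulate: soft-tissue artifacts, marker
occlusion and mislabeling, camera-specific noise spectra, inter-subject
style variation beyond Gaussian key-pose jitter, and object-interaction
gestures. Passing tests on synthetic data therefore validate the machinery
(geometry, calculus, scoring, bookkeeping), not field performance on any
particular video or mocap corpus.

## Problem sizes and determinism

The shipped tests run the solvers at deliberately small sizes — takes of
1–3 s at 20–30 Hz, benchmarks of 2–3 subjects and 4–10 takes per gesture,
50-pose IK recovery sweeps, 100k-draw distribution checks — which keep the
whole suite around half a minute while still exercising every code path at
realistic signal shapes. All stochastic stages consume the R RNG, so a
single `set.seed()` makes any pipeline run, benchmark or report
bit-reproducible; `split_takes()` and `design_report()` also accept explicit
seeds so reports are deterministic artifacts.

## Known limitations

- The kinematic model has no palm arch, no CMC mobility for non-thumb
  fingers, and straight-line phalanges; marker placements are joint centers
  rather than skin positions, so real-marker MDEs will exceed synthetic
  ones.
- Thumb geometry (base frame orientation, segment fractions) is a plausible
  fixture, not a fitted anthropometric model.
- The per-frame all-21 Kabsch alignment slightly biases flexed frames
  towards the rest pose; IK re-estimates the wrist, and the palm-anchored
  option eliminates the effect when the input is already model-compatible.
- The bias-instability filter constant (0.01 per sample) is a documented
  choice; only its neutral (zero) setting is covered by distributional
  guarantees.
- Importance scores are correlation-based and linear: nonlinearly coupled
  joints can score as independent. The best-vs-worst classifier comparison
  in the design report is the intended guard against over-trusting the
  ranking.
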