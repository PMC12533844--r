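---
title: "Behavior classification from pose tracks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior classification from pose tracks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fishbout)
```

This vignette is the package's own account of its methods: the model behind
each pipeline stage, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The data model

A `pose_track` holds per-frame positions of 8 anatomical keypoints — index 1
the snout, index 4 the body center, index 8 the caudal tail tip — for one
fish in one well, with frame rate (Hz), pixel size (µm/px), plate format (24
or 96), optional body length (mm), stimulus events, and a per-frame,
per-keypoint missingness mask. On disk, coordinates follow the image
convention (row, col); in memory they live in a right-handed Cartesian frame
(`x = col`, `y = −row`) so that "up" is +y and all downstream geometry uses
one convention. Frames are 0-based and every interval in the package is
half-open `[start, end)`; this removes off-by-one ambiguity from windowing,
bouts and response windows alike.

Missing keypoints are never dropped. `clean_track()` linearly interpolates
gaps of at most `max_gap` frames (default 5) between observed flanking
frames; longer gaps stay masked and any analysis window overlapping them is
flagged unusable. The cleaning procedure itself is a choice — the default is
the simplest interpolation consistent with short tracking dropouts — and the
gap cap is exposed.

## Windowing and egocentric alignment

A behavior unit is a 40-frame window (250 ms at 160 fps). A track of `T`
frames yields `T − 40` windows starting at frames `0 … T−41`; a 1600-frame
acquisition yields 1560. Note the deliberate quirk: `T − W + 1` complete
windows exist, but the `T − W` convention is kept because the pipeline's
bookkeeping (and its published window counts) follow it. Its only observable
consequence is that the final frame of an acquisition is covered by no
window and is therefore called `unknown`.

Alignment computes, per window, a single rigid transform from the first
frame — the rotation that takes the center→snout vector to +y, followed by
the translation of the center keypoint to the origin — and applies it to all
40 frames. Aligning to the origin rather than an "image center" is
immaterial: a constant offset disappears under the mean subtraction that
follows. The transform is rigid, so all intra-frame distances are preserved
and the representation is invariant to where in the well, and at what
orientation, the bout occurred; the test suite checks invariance to random
rigid motions at 1e-6 of a body length and canonical-pose placement at
1e-9. A window whose first-frame snout and center coincide has no defined
heading; it is marked unusable rather than silently aligned.

## Feature vectors and normalization

Aligned windows are flattened timepoint-major, then keypoint, then (x, y) —
index of `(t, k, c)` is `((t−1)·8 + (k−1))·2 + c` — giving 640 values for
`W = 40`. Two dataset-level scalars normalize them: `norm_max`, the maximum
absolute coordinate over usable windows, then `norm_mean`, the mean of the
max-scaled values; each coordinate becomes `v / norm_max − norm_mean`.
Scalar (not per-coordinate) constants are used deliberately: the spread of
coordinate values differs between plate formats (bigger wells, bigger
excursions), and one pair of scalars per format captures exactly that while
keeping the transform trivially invertible. Both scalars and the flattening
order are frozen into the trained classifier so inference reproduces
training-time scaling bit for bit.

## Discovery: KMeans and cluster roles

KMeans with `k = 9` on the normalized vectors is not expected to find
nameable behaviors — in practice clusters capture movement patterns — but it
reliably separates stationary from moving windows, which is what makes
targeted clip export for manual labeling efficient. Cluster roles are
assigned by a rule rather than inspection: a cluster whose mean implied
center-keypoint speed is strictly below 2 mm/s is stationary. The threshold
deliberately reuses the manual speed-bout threshold so one constant defines
"not moving" everywhere; the strict inequality sends a borderline cluster to
movement (the conservative direction for discovery, which wants movement
clips). If thresholding empties a role, the extreme cluster is reassigned so
both roles always exist. Initialization is seeded multi-start Lloyd
(`nstart = 10`), which is deterministic under the recorded seed; a k-means++
scheme would also do but is not available in base R and the determinism
contract is what matters here.

## The classifier

Training splits the labeled windows 90/10, stratified by class so small
classes survive into the test set, then fits PCA on the training split only
— centered, not whitened, keeping the smallest number of leading components
whose cumulative explained variance reaches 0.95 (the PCA seed, default
2023, is recorded; the exact eigendecomposition used here is deterministic
regardless). A random forest is fit on the projected features.

No decision-tree package is available in the supported dependency set, so
the forest is implemented in the package: bagged CART trees, Gini impurity,
a fresh random subset of `mtry = ⌊√p⌋` features at every split, trees grown
to purity (`min_split = 2`) with a depth cap of 30, 100 trees by default,
prediction by unweighted vote. These hyperparameters are ordinary
random-forest defaults; no tuning stage exists by design, and they are all
recorded in the classifier's provenance. Class probability is vote
fraction. Evaluation reports a row-normalized confusion matrix, per-class
F1, and macro-averaged F1 ("overall F1" is read as the macro average; the
per-class values are reported so any other convention can be computed).

The 24-well class set is `stationary, scoot, turn, AsLB, VsLB`; the 96-well
set merges scoot and turn into `movement` (in small wells, wall-following
turns are not reliably separable from self-generated turns). The two models
are the same code with different class sets and normalization scalars.

## Majority voting and bouts

A sliding window classifier emits one label per start frame, so a timepoint
is covered by up to 40 windows and raw output can alternate frame to frame
in ways no fish moves. Majority voting assigns each frame the most frequent
label among its covering windows. Ties break toward the earlier label in
the class-set order — stationary first — so ties default to the least
eventful call, the conservative direction for startle detection. Unusable
windows are labeled `unknown` and do not vote; uncovered frames are
`unknown`. The guarantees, all property-tested against a brute-force
enumeration oracle: a label carried by more than half the covering windows
always wins, voting never invents a label absent from the covering windows,
an isolated single-window flip inside a consistent run never survives, and
a call is never displaced more than one window width (250 ms) from its
source windows.

Bouts are maximal same-label runs strictly longer than `min_run = 5` frames
("exceeds 5"), while manual speed bouts use speed > 2 mm/s for *at least* 5
frames (≥ 5). The strict/non-strict asymmetry between the two definitions
is preserved deliberately as given; both thresholds are parameters. Runs
counted are voted frames (windows and timepoints are in 1:1 correspondence
after voting, so the distinction is nominal). `unknown` frames terminate
runs; a bout never spans one. Bouts plus gaps partition the acquisition
exactly.

## Kinematics

Speed is the center-keypoint displacement per frame times frame rate and
pixel size (mm/s); the center keypoint is used because it is the alignment
anchor. Heading is the direction of center→snout; instantaneous heading
change is its wrapped first difference in (−180°, 180°], per frame. The
caudal tail angle is the signed angle between the tailward trunk axis and
the caudal-most segment (keypoint 7 → 8): zero for a straight body. Which
keypoints define "tail angle" was an open choice; the caudal-most segment
maximizes sensitivity to tail-tip curvature and the index pair is an
argument. First-difference series keep length `T` by defining frame 0 as 0
rather than dropping it. Response windows are `[onset, onset + 0.25 s)` for
acoustic and `[onset, onset + 1.0 s)` for visual stimuli, onset frame
included; both exceed the established response latencies, so they capture
responders rather than measure latency.

## The synthetic world

The simulator exists so that every stage has ground truth. Its defaults are
the stated acquisition conditions: 160 fps, 10 s (1600 frames), body length
3.56 mm (24-well) / 3.85 mm (96-well), standard plate geometry (well radius
7.75 mm / 3.2 mm), pixel scale 37.8 µm/px (the scale consistent with the
platform's reported pixel-to-µm equivalences). Keypoint jitter has marginal
SD equal to the reported tracking accuracy per format — 69.6 µm (24-well),
133.1 µm (96-well) — applied as AR(1) noise with ρ = 0.995 because tracking
error is strongly correlated between consecutive frames; white jitter of
that magnitude would alias into ~16 mm/s apparent speed at 160 fps, which
real tracking does not show.

Archetype kinematic ranges are not printed anywhere and are
literature-informed choices, fixed once: scoots peak at 5–20 mm/s with under
25° of heading change; turns change heading 30–90° at under 5 mm/s; AsLB
(C-start-like) exceeds 90° within ≤ 40 ms at 30–60 mm/s; VsLB (O-bend-like)
makes a comparable heading change over 100–250 ms at 12–25 mm/s, with
longer onset latency (150–400 ms vs 5–20 ms). The VsLB duration is capped
at 34 frames so a complete bout fits inside one 40-frame window with room
for onset. A bout's speed profile is a half-sine; its heading change
follows a raised-cosine ramp completed by the archetype's time-to-peak;
the tail beats at ~20 Hz under the speed envelope plus a turn-side bend
proportional to the instantaneous heading change. Bodies are rigid
polylines of 7 equal segments; cumulative bends beyond 300° are clamped and
flagged.

Wall interaction is specular reflection of heading, with one behavioral
bias: a bout starting in the outer well (beyond 40% of the radius) turns
toward the well interior, as escape responses do. Without this, a C-start
launched near the wall gets its heading profile reflected mid-bout and its
realized kinematics genuinely resemble a fast scoot — an artifact of the
reflection model, not of the classifier.

Training data (`generate_labeled_dataset`) places each archetypal bout at a
*random phase* of its window, fully contained, as clips harvested from a
sliding window are. This matters: a classifier trained only on
onset-aligned bouts does not recognize the same bout half-way through a
window, and majority voting then collapses to stationary.

What the generator does **not** emulate: hydrodynamics, photorealistic
appearance, burst-glide substructure, habituation across trials, drug
effects (users emulate those by shifting archetype parameters), multi-fish
interactions, or tracking failures other than masked keypoints and AR(1)
jitter. A green synthetic benchmark therefore establishes that the pipeline
recovers the archetypes it defines under realistic noise — not that the
classifier would reach the same scores on real recordings, whose manual
labels embody kinematic boundaries no simulator guarantees.

## Numerical choices and degenerate inputs

Alignment tolerances: canonical pose within 1e-9, rigid-motion invariance
within 1e-6 body lengths (rotation composition is the only float-sensitive
step). Normalization refuses an all-zero dataset (`norm_max = 0`).
Prediction refuses feature vectors that are not exactly `W·16` long, and
labels unusable windows `unknown` with NA probabilities rather than
guessing. Stationary-role assignment uses a strict `< 2 mm/s`; exact
threshold equality is movement. Vote margins are winner minus runner-up
counts, 0 where only unknowns cover a frame. An all-masked keypoint is left
unchanged by cleaning, with a warning. Empty intervals are errors for
interval maxima; an empty response table is an error for rates.

## Known limitations

The forest is pure R; training at the default benchmark size (1000 windows,
100 trees) takes seconds, but very large clip libraries would want a
compiled implementation. The simulator's archetype boundaries are sharp
relative to real behavior, so synthetic scores are optimistic. Sub-window
timing of a call inherits up to one window width of uncertainty; analyses
needing ms-exact onsets should use the kinematic series directly. The
96-well merged `movement` class forfeits scoot/turn discrimination by
construction.
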