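---
title: "ethotox: models, conventions and design choices"
author: "ethotox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ethotox: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ethotox)
```

`ethotox` analyses open-field assays of a single walking insect in a circular
dish. This vignette documents the models behind each stage, the parameters
that matter (with units and defaults), the conventions adopted where several
were defensible, and what the synthetic generator does and does not emulate.

## 1. Automatic head/back labelling

The labeller is deliberately classical so that it can bootstrap a training
dataset with no manual annotation. Per frame:

1. **Segmentation** (`preprocessFrame`): 5×5 spatial Gaussian blur, then
   binarization keeping pixels *darker* than grey level 60 (the insect is
   dark on a light background). The blur sigma follows the common
   kernel-size rule `0.3 * ((k - 1)/2 - 1) + 0.8` (≈1.1 for k = 5) and is
   configurable. We read the "5×5" kernel as spatial; a third dimension
   would have no meaning for a single grey frame.
2. **Crop**: erosion operates on the insect's bounding-box crop (padded
   2 px). A `crop = FALSE` flag applies it to the full mask instead; the
   results are identical up to border effects, the crop is just faster.
3. **Progressive erosion** (`splitBody`): 0, 1, …, 10 erosions with a 3×3
   square structuring element (8-connected components throughout) until the
   largest component falls apart into ≥ 2 regions of at least 5 px² (the
   area floor ignores erosion debris; both values are configurable). If the
   binarized silhouette is already two regions — a very sharp neck — zero
   erosions are used.
4. **Assignment**: the smaller region is the head, the larger the back.
   This rule is orientation-free. An exact area tie is broken by the
   direction of recent motion (the leading region is the head) when motion
   is available, else by pixel scan order — deterministic either way.
5. **Part boxes**: the eroded cores underestimate the lobes, so every
   *pre-erosion* body pixel is assigned to the nearer eroded-core centroid
   (a two-site Voronoi assignment) and part bounding boxes are drawn over
   the assigned pixels. Centroids are reported from the eroded cores, which
   is what the downstream pose table consumes.
6. **No-split fallback**: a body that never splits within 10 iterations
   raises an error by default, mirroring the strict algorithm. An optional
   `fallbackAxisSplit` divides the blob by the line through its centroid
   perpendicular to the principal axis; it is off by default so failures
   are visible rather than silently approximated.

Dataset export (`exportDataset`) writes one text file per frame in the
normalized detection format (`class_id cx cy w h`, coordinates in [0, 1]),
a class map (head = 0, back = 1) and per-split manifests. Counts use floor
allocation with the remainder assigned to the training split: 1200 frames at
70:20:10 give exactly 840/240/120. Detection scoring (`evaluateDetection`)
matches greedily by descending IoU at a threshold (default 0.5); accuracy in
the detection context is TP/(TP+FP+FN) since true negatives do not exist;
average precision uses all-point interpolation of the precision–recall
curve (the envelope precision integrated over recall), and mAP averages AP
over the two classes. With no truth and no predictions all metrics are 1 by
convention.

## 2. Trajectory conditioning

`trackVideo` applies the labeller per frame; the body centroid is the
head/back midpoint. Failed frames get likelihood 0 and are linearly
interpolated when the gap is at most `maxGap` frames (default 5), else left
missing — interpolation was chosen over frame-dropping so that time-based
features keep a uniform clock, and interpolated frames remain identifiable
by their zero likelihood.

- **Smoothing**: centred 3-frame rolling mean per coordinate; endpoints use
  truncated windows so length is preserved; window 1 is the identity.
- **Low-pass speed filter**: frame-to-frame speeds above `speedCap`
  (default 50 mm/s, configurable) are treated as tracking errors. The
  offending point is removed and re-interpolated; a single teleport spike
  breaks two consecutive steps, so only the first point of each offending
  run is removed per pass before re-checking. The number of corrected
  frames is reported. 50 mm/s is roughly 12 body lengths per second for a
  4 mm insect — beyond sustained walking speeds of small Coleoptera — and
  `stopSpeed` (default 0.5 mm/s) separates stop bouts from drift noise.
- **Segment**: analyses default to the central 2 minutes of a recording
  (`centralSegment`), discarding acclimation at the start and disturbance
  at the end.

## 3. Arena geometry and behavioural features

The dish is fitted as the circumcircle of three rim points
(`fitCircle`; collinear points are rejected). Conventions, chosen once and
used everywhere:

- **Calibration**: 1 px = 0.055 mm and 60 fps by default; distance is the
  summed body-centroid displacement × calibration (mm), speed is
  displacement × fps (mm/s), acceleration is the speed difference × fps
  (mm/s²) summarised as the mean absolute value (a direction-free measure
  of speed changes). Stop time counts frames whose speed is below
  `stopSpeed`, using a per-frame speed series in which the first frame
  carries the first inter-frame speed, so a fully stationary recording is
  stopped for its whole duration.
- **Zones**: inner zone radius 2/3 r; a point exactly on the boundary
  counts as inner. Inner + outer time equals the analysed duration by
  construction.
- **Wall band**: "contact" means distance-to-centre ≥ r − 1 mm. Exact
  equality has measure zero, so the tolerance is read as a band, as in the
  wall-following literature. A thigmotaxis *event* is an entry — a
  transition from non-contact to contact — counted only when the contact
  run lasts ≥ 2 frames (debouncing single-frame jitter); a trajectory that
  starts in contact counts one entry. Contact *time* counts all contact
  frames. Antennal events are counted per side (lateralization); wall
  contact time uses the head.
- **Angles and turns**: the body axis angle is the quadrant-resolved
  arctangent of head minus back, with the image y axis negated so
  counter-clockwise is positive — "left" turns are counter-clockwise in
  arena coordinates. Frame-to-frame differences are wrapped to (−π, π];
  cumulative rotation is their running sum. A full left (right) turn is
  counted each time the running sum crosses a new positive (negative)
  multiple of 2π — net excursions, so jitter does not accumulate into
  spurious turns; a small ε = 1e-9 keeps an exact full turn from being
  lost to floating-point rounding. Reversing a series swaps the two
  counts. Coincident head/back positions carry the previous angle forward
  and are flagged.

The classifier input is a 10-feature vector per individual: distance,
mean and max speed, mean |acceleration|, stop time, inner and outer zone
times, wall contact time, and left/right antennal thigmotaxis counts. Turn
counts and cumulative rotation are reported in the feature table but not
fed to the classifier by default.

## 4. Probit concentration–mortality analysis

Mortality is modelled as binomial with probit(p) = a + b·log₁₀(dose), fitted
by maximum likelihood (`stats::glm` with a probit link). Dose groups with
0% or 100% kill enter through the exact binomial likelihood; no
empirical-probit transform or Berkson correction is needed. With natural
control mortality c, the Abbott-corrected response
p = c + (1 − c)·Φ(a + b·x) is fitted by direct likelihood maximisation
(`optim`, BFGS, Hessian-based covariance). LC_p = 10^((Φ⁻¹(p) − a)/b);
confidence limits are delta-method on the log₁₀ scale (Fieller limits were
considered and omitted: at the sample sizes of interest the two differ far
less than the sampling noise). Goodness of fit is the Pearson χ² on
(#doses − 2) degrees of freedom.

**Precision at typical bioassay designs.** With 7 concentrations on a
half-decade ladder and 30 insects per concentration, the Fisher information
of this design bounds the sampling sd of log₁₀ LC₅₀ at roughly 0.04–0.07
for realistic slopes (b ≈ 1.5–3), i.e. the LC₅₀ from a single such assay is
only determined to within ±10–15% about two-thirds of the time. The test
suite therefore validates the estimator by checking that its empirical
recovery rate matches its own asymptotic (Fisher-information) prediction,
rather than an arbitrary fixed rate: correctness of the implementation is
testable; the precision ceiling is a property of the design, not of the
code. Tighter LC estimates require more insects, more replicates, or
concentrations concentrated near the LC of interest.

## 5. Nonparametric group statistics

Per feature: a Shapiro–Wilk gate (delegated to `stats::shapiro.test`;
constant samples cannot be tested and are flagged as non-normal), a
Kruskal–Wallis omnibus test (delegated to `stats::kruskal.test`; identical
observations give H = 0, p = 1), and a Dunn post hoc implemented from the
pooled-rank formula with tie correction, two-sided p values, and Holm
step-down adjustment. The Holm family is all pairwise comparisons *within
one feature* — features answer separate questions and are reported
separately, so correcting across features would conflate the two error
rates. Dunn's test is two-sided: the direction of group differences is not
assumed.

## 6. Nested cross-validated classification and exact Shapley values

Binary group comparisons use stratified 4-fold outer CV for generalization
and, per outer-training set, a stratified 4-fold inner CV grid search
selecting hyperparameters by mean inner accuracy. Grids: SVM cost on the
decade ladder {0.01, 0.1, 1, 10, 100} (endpoints fixed, decade steps the
natural fill) with rbf and linear kernels; random forest with
{20, 50, 100, 150, 200, 250, 300} trees and maximum depth 2–5 (the `ranger`
backend exposes a true depth control); KNN with odd k from 3 to 15.
Accuracy ties break toward the simpler setting — smaller C / linear kernel,
fewer and shallower trees, larger k — by ordering the grid simplest-first.
Features are standardized with means and sds fitted on the respective
training portion only (zero-variance columns are centred and left at zero),
so no information leaks from test folds; a sentinel-feature test in the
suite guards this property. Outer-fold predictions are pooled into a single
confusion matrix — the natural analogue of reporting one overall confusion
matrix per comparison — from which accuracy, precision, recall and F1 are
computed. All folds and learners are seeded; identical seeds give identical
results.

Shapley attributions are **exact**: the value function v(S) is the mean
model output over background-completed hybrids (features in S from the
explained sample, the rest from each background row), enumerated over all
2^d coalitions (d ≤ 15; wider inputs are refused with a pointer to
sampling approximations, which are out of scope). Efficiency —
attributions summing to prediction minus baseline — holds to 1e-8 by
construction and is asserted in the tests, as is the closed form for
additive models. For KNN the explained output is the neighbourhood
proportion of the positive class rather than the hard label (attributions
on step functions are uninformative). Per outer fold, the background is the
fold's training portion capped at 64 rows by seeded subsampling; explained
samples are the fold's test rows; summaries report the mean |φ| per
feature.

## 7. The synthetic arena generator

The generator exists so every stage can be validated against exact ground
truth. It emulates a stop-and-go correlated random walk in a dish:

| parameter | units | control | lc10 | lc30 | meaning |
|---|---|---|---|---|---|
| `meanSpeed` | mm/s | 6.0 | 4.2 | 3.0 | mean walking speed while moving |
| `speedDispersion` | — | 0.45 | 0.45 | 0.45 | between-individual lognormal sd |
| `turnKappa` | — | 150 | 150 | 150 | heading concentration; per-frame turn sd = 1/√κ |
| `stopRate` | /frame | 0.02 | 0.05 | 0.08 | go → stop probability |
| `goRate` | /frame | 0.10 | 0.06 | 0.05 | stop → go probability |
| `wallBias` | — | 0.80 | 0.60 | 0.45 | wall-following probability in the band |

The treated presets mirror the qualitative pattern of sublethal exposure in
walking insects — lower speed, lower go-state occupancy (0.83 / 0.55 / 0.38
for control / lc10 / lc30), weaker wall-following, hence less distance,
more stopping, fewer thigmotactic entries and more time in the dish centre
— with the lc10 preset intermediate but closer to lc30, so that
classification separates control from either treatment more easily than
the two treatments from each other. The magnitudes are free design
parameters (no quantitative effect sizes are available to copy); they were
fixed once, with `speedDispersion = 0.45` giving realistic between-animal
overlap rather than trivially separable groups.

Mechanics: gamma-distributed step lengths (shape 4, mean `meanSpeed`/fps);
wrapped-normal heading increments while moving only (a stopped insect holds
its pose); inside the wall band the walker either steers to the nearest
tangent with a small radial correction that regulates toward a wall-hugging
radius (probability `wallBias`) or reflects away; turning is rate-limited
to 0.22 rad/frame so rigidly attached keypoints (head at 0.42 L, antenna
tips at 0.25 L beyond the head, ±25° off-axis) never move faster than the
downstream speed cap; the back centroid is clamped to r − 0.185 L (body
half-width plus a standoff) and the head to r − 0.10 L, braking at the wall
when needed, so head and back centroids always stay inside the dish.

Rendering: two overlapping ellipses (back semi-axes 0.30 L × 0.17 L, head
0.15 L × 0.12 L at offset 0.42 L, leaving a narrow neck where erosion
separates the lobes), body grey 10 on background grey 110 — the midpoint of
those levels is the fixed binarization threshold 60, i.e. the scene
luminance the segmentation algorithm is designed for — plus additive
Gaussian noise (default sd 5). The exact silhouette, per-lobe masks and
bounding boxes are returned with each frame.

What the generator does **not** emulate — and hence what passing tests do
and do not show about real data: no photorealistic texture, shadows,
reflections or the dark dish rim; antennae are rigid offsets (no antennal
kinematics), and antenna *tips* may geometrically cross the rim by a few px
while wall-following, standing in for antennal wall contact; no
mechanistic sex differences (sex labels exist for bookkeeping); no
occlusions or multi-insect frames. Tests passing on synthetic frames show
the algorithms are implemented correctly and behave as designed under
controlled conditions; they do not certify performance on real video,
which is the role of the trained-network stage that consumes the exported
dataset.

## 8. Problem sizes and numerical choices

Rendering-based tests run in a compact 12 mm-radius dish at the native
0.055 mm/px calibration, so the insect has its real pixel size (~73 px body
length — the regime the 10-iteration erosion budget is designed for) while
frames stay ~444×444 px; feature and classification tests use the full
25 mm dish without rendering (trajectories only), with cohorts of
3 groups × 2 sexes × 16 replicates × 2400 frames. The labelling acceptance
check uses a 200-frame synthetic test set at noise sd 5; null-distribution
checks use 200–2000 replicates.

Degenerate inputs are handled explicitly: empty frames raise a no-insect
error; a never-splitting body raises a no-split error (fallback off by
default); coincident head/back carries the previous angle; constant
samples are flagged by the normality gate; zero-variance features
standardize to zero; all-or-nothing bioassays raise a non-estimable error;
undefined metric ratios return NaN with a warning.

## 9. Known limitations

- The classical labeller assumes one dark insect on a light background
  inside the dish; it does not handle occlusions, reflections, multiple
  animals or non-circular arenas.
- Antennal keypoints come from ground truth (or an external pose table),
  not from the classical labeller — in a real deployment they come from a
  dedicated pose-estimation network.
- Single-assay LC estimates at 7×30 designs carry ±10–15% sampling error
  (section 4); treat reported confidence limits, not the point estimate,
  as the result.
- Exact Shapley enumeration is exponential in the number of features; the
  implementation refuses d > 15 by design.
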