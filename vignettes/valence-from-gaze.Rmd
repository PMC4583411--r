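---
title: "Recognizing image valence from eye movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing image valence from eye movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazevalence)
```

## The problem

When people view an emotionally charged picture, their eye movements change:
negative content tends to narrow the spatial spread of fixations, lengthen
dwell times, and alter saccade kinematics and turning behavior. `gazevalence`
turns those regularities into a classifier: given the fixation sequences of
many observers on an image, it predicts the image's valence class —
*unpleasant*, *neutral* or *pleasant* — as derived from mean ratings on the
1–9 Self-Assessment Manikin (SAM) scale. Ratings in [3.8, 5.8] are neutral
(boundaries inclusive, a documented convention since the band's inclusivity
is not standardized), below unpleasant, above pleasant; the three classes
partition the scale exhaustively.

The reference setting is free viewing of 1024 × 768 px affective photographs
for 5 seconds, with roughly 25 observers per image and fixations of at least
100 ms. The curated study set shipped in `extdata` (95 IAPS picture IDs:
47 neutral, 24 pleasant, 24 unpleasant, all people-and-daily-activity
scenes) defines the class proportions every default in the package assumes.

## Data model

A **fixation** is a dwell `(x, y, t_start, t_end)`; coordinates are 0-based
pixels, origin top-left, y growing downward — one convention shared by every
module. A **saccade** is approximated as the straight jump between two
consecutive fixations of one observer on one image: it starts where (and
when) fixation *i* ends and lands where (and when) fixation *i + 1* starts.
This timing convention — the saccade occupies the inter-fixation gap — is a
package choice; recorded gaze tables rarely expose saccade events directly,
and the gap is the only interval the fixation table determines. A zero-length
gap is legal and simply yields a zero-duration saccade, which is excluded
from the velocity histogram (its velocity is undefined) but from nothing
else.

I/O is plain CSV: `image_id,observer_id,x,y,t_start_ms,t_end_ms` plus a label
table `image_id,mean_valence[,valence_class]`. Writing is deterministic
(image, observer, onset order), and `read_fixation_table()` rejects rows that
violate the invariants, naming the offending row numbers.

## Feature representations

Ten per-image blocks, pooled over all observers of the image, concatenate to
an 872-dimensional vector (`feature_blocks()` gives the exact layout):

| block | dims | content |
|---|---|---|
| `saliency_map` | 300 | 15 × 20 coarse fixation-density map |
| `top10_salient` | 20 | ten strongest map maxima, normalized (x, y) |
| `fixation_histogram` | 256 | 16 × 16 spatial grid counts |
| `saliency_histogram` | 10 | map values at fixations, binned over [0, 1] |
| `fixation_duration_hist` | 60 | dwell times |
| `saccade_duration_hist` | 60 | inter-fixation gaps |
| `saccade_slope_hist` | 30 | undirected line angles, 6°/bin over 0–180° |
| `saccade_length_hist` | 50 | Euclidean jump lengths |
| `saccade_velocity_hist` | 50 | length / duration |
| `saccade_orientation_hist` | 36 | angle between successive saccades |

The **saliency map** smooths the pooled fixation count map with an isotropic
Gaussian of σ = 10 px (about 2° of visual angle in the reference viewing
geometry) and rescales to max 1. The smoothing adds one truncated (4σ)
separable bump per fixation — algebraically a convolution of the count map,
but linear in the number of fixations rather than pixels. The truncation
error is below `exp(-8)` of a bump's peak, far inside the tolerances used
anywhere downstream. The coarse 15 × 20 map averages blocks of 51.2 px with
area weighting (cells do not align with pixel boundaries) and is min–max
rescaled; it is flattened row-major.

**Top-10 salient locations** implement inhibition of return: ten times, take
the global argmax of a working copy, record its location normalized by image
size, and zero a disk of radius 2σ around it. Ties break toward the smallest
row-major index (topmost row, then leftmost column), so a constant map yields
(0, 0) first; a fully suppressed map keeps picking value-0 locations under
the same rule. The 2σ radius matches the suppression of one fixation's
footprint.

**Histograms** place `n` bin centers uniformly over a property range,
assign each value to the nearest center (half-way ties to the lower center),
and clip out-of-range values into the end bins so no event is lost. They are
normalized to probability mass by default (`normalize = FALSE` gives raw
counts); an empty input is the all-zero vector, which keeps images without
saccades representable. Ranges are *dataset-global conventions* frozen in
`default_binning_schemes()` — fixation durations 100–2000 ms, saccade
durations 0–2000 ms, lengths 0 to the image diagonal, velocities 0–10 px/ms,
slopes 0–180°, orientations 0–180°. Per-image ranges would erase exactly the
scale differences (longer unpleasant saccades, longer dwells) that the
mean-value analysis shows are class-informative, and would make vectors of
different images incomparable.

**Orientation binning.** The angle between successive saccades is computed as
the arccosine of the cosine similarity of their displacement vectors and so
lives in [0°, 180°]; 36 bins give a 5° quantization. A 36-bin 10° quantization
would require a 360° range, which the arccosine cannot produce; the package
therefore defaults to 36 × 5° over 0–180° and offers the signed-turning-angle
convention (`saccade_orientation(signed = TRUE)` with
`default_binning_schemes(orientation_range = 360)`) for users who want the
full circle. Events with an undefined value — zero-displacement slopes,
zero-duration velocities, degenerate orientation pairs — are dropped from
their own histogram only, never from the scanpath.

**Mean-value features** are the traditional behavioral representation: the
per-image mean of each of six properties, min–max normalized to [0, 1]
*across the images of the dataset*. One image gives no normalization (an
error); a property constant across images maps to 0 by convention.

Pooling across observers before histogramming (rather than averaging
per-observer vectors) follows the distribution-across-observers reading of
the feature definitions; it also makes features invariant to observer order,
which the tests assert.

## Classification protocol

Classification is one-versus-rest: three binary soft-margin SVMs (via
`e1071`/libsvm), one per class, predictions by the largest decision value
(ties to the first class). Features are standardized to zero mean and unit
variance on each fold's training rows — the blocks live on wildly different
scales, and margin classifiers are not scale-invariant. The generalization
protocol is 10 repetitions of 10 folds with train/validation/test ratios
0.9/0.05/0.05; validation and test sets are drawn with an *equal number of
items per class* (`max(1, round(ratio × smallest class size))` each), a
conservative stratified draw that keeps the test confusion matrices balanced
across folds. Folds are independent stratified draws (a disjoint partition is
impossible with balanced 5% draws from unbalanced classes) and deterministic
under the plan's seed.

SVM hyperparameters are chosen per fold on the validation split from small
grids (`svm_grid()`): cost {0.1, 1, 10} for linear; cost × degree {2, 3} for
polynomial; cost {1, 10} × γ ∈ {0.5, 1, 2}/d for RBF. The grids are package
choices — the validation split exists precisely to select them — kept small
because 95-image folds saturate quickly.

Performance is summarized by **multiclass Bookmaker informedness**: per class,
Youden's J = recall + inverse recall − 1 in the one-versus-rest decomposition,
averaged with prevalence weights (row sums / total). It is +1 for a perfect
classifier, exactly 0 whenever predictions are independent of the truth
(proportional rows), −1 for a perversely incorrect binary classifier, and is
invariant to multiplying all counts by a constant. Internally each J is
computed as `tp/pos − fp/neg`, which is algebraically the same and returns an
exact 0.0 on truth-independent matrices. An unweighted macro average is
available via `weighted = FALSE`. Accuracy (trace/total) is reported
alongside, as the more familiar but prevalence-sensitive companion.

## Feature reduction and selection

* `variance_reduce()` — PCA (centered) or SVD (uncentered) fit on training
  rows only, keeping the minimal leading components whose cumulative
  explained variance reaches the threshold (default 90%).
* `sequential_select()` — greedy forward (SFS) or backward (SBS) wrapper
  search, one change per step, stopping when no single change strictly
  improves the objective; ties break to the lowest index, making the
  trajectory deterministic. The stop-at-no-improvement rule (rather than a
  fixed target size) is consistent with the reduction ratios wrapper methods
  typically report on this problem.
* `ga_select()` — elitist binary GA: tournament selection (size 2), uniform
  crossover 0.8, bit mutation 0.02, population 30, 100 generations.
* `pso_select()` — mutated binary PSO: sigmoid velocity transfer, inertia
  0.72, c1 = c2 = 1.49, velocity clamp 4, bit-flip mutation 0.05, swarm 30,
  100 iterations.

The evolutionary defaults are standard textbook settings, exposed as
arguments, since no authoritative values exist for this task in the open
literature the package draws on. Both optimizers repair all-zero masks by
activating one random bit, are deterministic under their seed, and preserve
the best solution (elitism / global best), so their best-fitness trajectories
are monotone — properties the test suite asserts, along with recovery of
exhaustively enumerable 6-bit optima.

The wrapper objective (`wrapper_objective()`) scores a candidate mask by
validation Bookmaker on **one fixed fold**, a deliberate cost bound: a full
inner CV per candidate would multiply the search cost by the fold count.
Wrapper searches run at block granularity (10 bits) by default and dimension
granularity (872 bits) in the full profile. `contribution_analysis()`
aggregates dimension-granularity masks across runs into the mean fraction of
each block's dimensions selected, the package's feature-contribution ranking.

## The synthetic generator

Real affective gaze corpora are not redistributable, so `generate_gaze()`
produces labeled recordsets with the class-conditional structure the
literature describes, at the study scale by default: 24/47/24 images,
25 observers, 1024 × 768 px, 5 s windows, ≥ 100 ms fixations. Per image, 2–4
attractor points anchor a scanpath simulation that alternates persistent
moves (previous direction plus a wrapped-normal turning angle; log-normal
step length) with relocations to another attractor (probability 0.35);
fixation durations are log-normal floored at 100 ms with 20–60 ms gaps.
A containment rule redirects moves that stray beyond 2.5 × the class's
spread radius back toward the attractor, so spatial spread stays governed by
the spread parameter even for classes with long saccades.

Class effects scale with a single `effect` magnitude in [0, 1] (0 is the
null mode, in which all classes share one generative process):

* spread × (1 ∓ 0.40) — attentional narrowing: unpleasant narrower,
  pleasant wider;
* duration log-mean + 0.30 / − 0.15 — longer dwells for unpleasant images;
* saccade scale × (1 + 0.35) / (1 − 0.20) — longer unpleasant saccades;
* turning-angle SD × (1 ∓ 0.35) — straighter (more persistent) unpleasant
  scanpaths.

Directions follow the cited behavioral findings; magnitudes (15–40%) were
chosen once as plausible medium-to-large behavioral effect sizes and are not
tuned. Ratings are drawn uniformly inside each class's SAM band so labeling
and rating pathways stay consistent. The generator claims *no physiological
realism*: it reproduces the marginal statistics the features measure
(spread, durations, lengths, angles) but not image content, inter-observer
idiosyncrasy, arousal as a second affective dimension, or temporal
nonstationarity within a trial. Passing tests therefore demonstrate that the
pipeline detects the planted class-conditional structure — not that real
images are classifiable at any particular rate.

## Numerical choices and degenerate inputs

* Fixation validation tolerates 1e-6 ms of floating-point slack on the
  100 ms minimum; timestamps are sums of random draws.
* Histogram half-way ties go to the lower bin center, matching the
  lowest-index convention used everywhere else.
* `bookmaker()` on an empty matrix is an error; a class with an empty row
  contributes informedness 0 at zero weight.
* A constant feature dimension passes through standardization unscaled, and
  a constant matrix is rejected by `variance_reduce()` (no variance).
* Scanpaths that would be empty (window shorter than the first draw) keep a
  single minimum-duration fixation so every observer appears in the data.

## Problem sizes used by the shipped checks

The test suite exercises the full study scale where it matters: the
end-to-end checks run the 24/47/24 × 25-observer generator with the default
10 × 10 plan for the strong-effect and chance-calibration results, a lighter
2 × 10 plan with three replicate datasets per effect level for the
monotonicity curve, and a 60 × 872 planted-signal matrix with five
selection runs for the contribution ranking. Oracle comparisons (saliency
maps, histograms) run on 64 × 48 canvases, where brute force is exact and
cheap. These sizes are the package's reproducibility statement: every number
in the README was produced by re-running them.

## Known limitations

* The equal-per-class draw is one reading of "conservative sampling"; other
  stratification schemes would change fold composition slightly.
* Wrapper searches at dimension granularity are expensive in pure R; the
  block-granularity default trades resolution of the contribution analysis
  for tractability.
* The SVM grids are small by design; exhaustive tuning on 95-image datasets
  mostly rewards validation-set noise.
* Order-sensitive (temporal) scanpath encodings, bottom-up image saliency,
  and probabilistic calibration of the classifiers are out of scope.
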