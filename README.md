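# gazevalence

Recognizing the affective **valence** of an image — *unpleasant*, *neutral*
or *pleasant* — from the eye movements of the people who viewed it.

When observers free-view emotionally charged pictures, their gaze changes in
measurable ways: negative content narrows the spatial spread of fixations
("attentional narrowing"), lengthens dwell times, and alters saccade lengths
and turning behavior. `gazevalence` implements a complete analysis pipeline
built on those regularities:

* **Gaze data model** — fixations `(x, y, t_start, t_end)`, saccades derived
  as the jumps between consecutive fixations, plain-CSV I/O with validation,
  and valence labeling from mean ratings on the 1–9 SAM scale (neutral in
  [3.8, 5.8], unpleasant below, pleasant above).
* **Ten feature representations** per image, pooled over observers,
  concatenating to an 872-dimensional vector: a 15 × 20 fixation-density
  (saliency) map smoothed with a σ = 10 px Gaussian, the top-10 salient
  locations extracted by inhibition of return, a 16 × 16 spatial fixation
  histogram, a saliency-value histogram, and histograms of fixation duration
  (60 bins), saccade duration (60), slope (30), length (50), velocity (50)
  and orientation (36) — plus the six traditional normalized mean-value
  features.
* **Classification** — one-versus-rest SVMs (linear / polynomial / RBF) under
  10 × 10 repeated cross-validation with 0.9/0.05/0.05
  train/validation/test splits and equal per-class draws, scored by
  **multiclass Bookmaker informedness**: the prevalence-weighted average of
  per-class Youden's J (recall + inverse recall − 1), which is +1 for a
  perfect classifier, exactly 0 when predictions are independent of the
  truth, and −1 for a perversely incorrect binary one.
* **Feature reduction and selection** — PCA/SVD at a 90% explained-variance
  threshold, sequential forward/backward selection, an elitist binary
  genetic algorithm and a mutated binary PSO, plus a contribution analysis
  that ranks the ten blocks by the fraction of their dimensions the wrapper
  methods retain.
* **Synthetic gaze generator** — class-conditional scanpath simulation
  (spread, durations, saccade lengths, turning angles) at the reference
  study scale (24/47/24 images, 25 observers, 1024 × 768 px, 5 s viewing),
  with a single effect-magnitude dial whose 0 setting is an exact null mode.
  The curated 95-image IAPS study set (47 neutral / 24 pleasant /
  24 unpleasant picture IDs) ships as a plain CSV.

## Worked example

```r
library(gazevalence)

# simulate a small labeled study: 28 images, 10 observers each
rec <- generate_gaze(synthetic_config(n_images = c(8, 12, 8),
                                      n_observers = 10), seed = 42)
rec
#> <gaze_recordset> 4467 fixations, 28 images, 10 observers, 1024 x 768 px
#>   valence_class     n
#> 1 unpleasant        8
#> 2 neutral          12
#> 3 pleasant          8

feats <- extract_features(rec)   # 28 x (1 + 872) tibble
labels <- rec$labels$valence_class[match(feats$image_id, rec$labels$image_id)]

plan <- make_cv_plan(labels, repeats = 3, folds = 8, seed = 42)
ev <- train_eval(feats, plan, kernel = "linear")
glance(ev)
#>   kernel n_folds mean_bookmaker se_bookmaker mean_accuracy se_accuracy
#> 1 linear      24          0.542       0.0792         0.694      0.0528

aggregate_folds(ev)$pooled_confusion
#>             predicted
#> truth        unpleasant neutral pleasant
#>   unpleasant         21       3        0
#>   neutral             3      16        5
#>   pleasant            0      11       13
```

A mean Bookmaker of 0.54 says the classifier operates far above chance
(0 = guessing, 1 = perfect): across the 24 test folds it recovered the
planted affective structure, with most confusion between neutral and
pleasant images — the pooled confusion matrix counts every test prediction
of every fold. Accuracy (69%) is reported alongside but, unlike Bookmaker,
is inflated by class imbalance.

Feature-level questions use the same objects:

```r
run_baseline(rec, kernels = "linear", repeats = 3, folds = 8)  # per-block scores
rep <- run_fusion(feats, labels, methods = c("full_set", "pca", "sbs"),
                  repeats = 3, folds = 8, seed = 1)
rep$contribution      # which blocks does selection keep?
autoplot(rep)         # method x kernel comparison
```

`autoplot()` methods exist for saliency maps, baseline reports, fusion
reports and contribution reports; `tidy()`/`glance()` follow broom
conventions.

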