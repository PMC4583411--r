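test_that("generated recordsets satisfy every fixation invariant", {
  cfg <- synthetic_config(n_images = c(3, 4, 3), n_observers = 6,
                          width = 512, height = 384)
  rec <- generate_gaze(cfg, seed = 2)
  fx <- rec$fixations
  expect_true(all(fx$t_end_ms - fx$t_start_ms >= 100 - 1e-6))
  expect_true(all(fx$x >= 0 & fx$x < 512))
  expect_true(all(fx$y >= 0 & fx$y < 384))
  expect_true(all(fx$t_end_ms <= cfg$window_ms))
  expect_equal(dplyr::n_distinct(fx$image_id), 10)
  # ratings are consistent with the class labels
  expect_equal(as.character(label_valence(rec$labels$mean_valence)),
               as.character(rec$labels$valence_class))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_images = c(2, 2, 2), n_observers = 3)
  expect_identical(generate_gaze(cfg, seed = 10), generate_gaze(cfg, seed = 10))
  expect_false(identical(generate_gaze(cfg, seed = 10),
                         generate_gaze(cfg, seed = 11)))
})

test_that("null mode erases class differences; full effect orders the spread", {
  # effect = 1: RMS spread around the per-image centroid is ordered
  # unpleasant < neutral < pleasant
  spread_by_class <- function(rec) {
    per_img <- rec$fixations %>%
      dplyr::group_by(image_id) %>%
      dplyr::summarise(spread = sqrt(mean((x - mean(x))^2 + (y - mean(y))^2)),
                       .groups = "drop") %>%
      dplyr::left_join(rec$labels, by = "image_id")
    tapply(per_img$spread, per_img$valence_class, mean)
  }
  cfg1 <- synthetic_config(n_images = c(6, 6, 6), n_observers = 20, effect = 1)
  s1 <- spread_by_class(generate_gaze(cfg1, seed = 3))
  expect_lt(s1[["unpleasant"]], s1[["neutral"]])
  expect_lt(s1[["neutral"]], s1[["pleasant"]])

  # effect = 0: class-conditional duration / length / spread means are
  # statistically indistinguishable
  cfg0 <- synthetic_config(n_images = c(8, 8, 8), n_observers = 20, effect = 0)
  rec0 <- generate_gaze(cfg0, seed = 4)
  fx <- dplyr::left_join(rec0$fixations, rec0$labels, by = "image_id")
  p_dur <- stats::kruskal.test(fx$t_end_ms - fx$t_start_ms,
                               fx$valence_class)$p.value
  expect_gt(p_dur, 1e-4)
  sc <- derive_saccades(rec0)
  sc <- dplyr::left_join(sc, rec0$labels, by = "image_id")
  p_len <- stats::kruskal.test(saccade_length(sc), sc$valence_class)$p.value
  expect_gt(p_len, 1e-4)
})

test_that("class-conditional statistics recover the configured parameters", {
  cfg <- synthetic_config(n_images = c(4, 4, 4), n_observers = 100)
  rec <- generate_gaze(cfg, seed = 5)
  fx <- dplyr::left_join(rec$fixations, rec$labels, by = "image_id")
  pars <- gazevalence:::class_params(cfg)
  for (cl in levels(rec$labels$valence_class)) {
    med <- stats::median(fx$t_end_ms[fx$valence_class == cl] -
                           fx$t_start_ms[fx$valence_class == cl])
    want <- exp(pars$meanlog_dur[pars$valence_class == cl])
    expect_lt(abs(med - want) / want, 0.10)
  }
})

test_that("label permutation preserves the label multiset and the gaze data", {
  rec <- small_synthetic(seed = 8)
  perm <- permute_valence_labels(rec, seed = 1)
  expect_identical(perm$fixations, rec$fixations)
  expect_equal(sort(as.character(perm$labels$valence_class)),
               sort(as.character(rec$labels$valence_class)))
  expect_equal(sort(perm$labels$mean_valence), sort(rec$labels$mean_valence))
  expect_identical(permute_valence_labels(rec, seed = 1),
                   permute_valence_labels(rec, seed = 1))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(window_ms = 50), "window")
  expect_error(synthetic_config(effect = 2), "effect")
  expect_error(synthetic_config(n_images = c(0, 1, 1)), "positive")
})
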