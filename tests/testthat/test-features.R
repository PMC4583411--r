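test_that("the concatenated feature vector has 872 dimensions in fixed blocks", {
  blocks <- feature_blocks()
  expect_equal(blocks$size, c(300L, 20L, 256L, 10L, 60L, 60L, 30L, 50L, 50L, 36L))
  expect_equal(n_feature_dims(), 872L)
  expect_equal(length(feature_dim_names()), 872L)

  rec <- small_synthetic(seed = 1)
  feats <- extract_features(rec, sigma = 4)
  expect_equal(ncol(feats) - 1L, 872L)
  expect_equal(nrow(feats), 7)
  expect_equal(names(feats)[-1], feature_dim_names())
  # histogram blocks are probability mass functions when events exist
  X <- as.matrix(feats[, -1])
  for (b in c("fixation_histogram", "saliency_histogram",
              "fixation_duration_hist", "saccade_length_hist")) {
    cols <- blocks$start[blocks$block == b]:blocks$end[blocks$block == b]
    sums <- rowSums(X[, cols])
    expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  }
})

test_that("a single-fixation image zeroes the saccade blocks only", {
  fx <- make_fixations(50, 40, 0)
  lb <- tibble::tibble(image_id = "img1", mean_valence = 5)
  rec <- gaze_recordset(fx, lb, width = 200, height = 150)
  v <- gazevalence:::extract_image_features(
    rec$fixations, derive_saccades(rec$fixations), 200, 150,
    schemes = default_binning_schemes(200, 150), sigma = 4
  )
  blocks <- feature_blocks()
  for (b in grep("^saccade", blocks$block, value = TRUE)) {
    cols <- blocks$start[blocks$block == b]:blocks$end[blocks$block == b]
    expect_equal(sum(v[cols]), 0)
  }
  fixcols <- blocks$start[blocks$block == "fixation_histogram"]:blocks$end[blocks$block == "fixation_histogram"]
  expect_equal(sum(v[fixcols]), 1)
})

test_that("feature extraction is invariant to observer order", {
  rec <- small_synthetic(seed = 4)
  f1 <- extract_features(rec, sigma = 4)
  shuffled <- rec
  set.seed(1)
  shuffled$fixations <- rec$fixations[sample(nrow(rec$fixations)), ]
  shuffled$fixations <- dplyr::arrange(shuffled$fixations,
                                       image_id, observer_id, t_start_ms)
  rec2 <- gaze_recordset(shuffled$fixations, rec$labels,
                         width = rec$width, height = rec$height)
  f2 <- extract_features(rec2, sigma = 4)
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("rigid motions preserve lengths and orientations, shift slopes", {
  set.seed(21)
  n <- 8
  fx <- make_fixations(runif(n, 200, 400), runif(n, 200, 400),
                       seq(0, by = 400, length.out = n))
  sc <- derive_saccades(fx)
  theta <- 30 * pi / 180
  rot <- function(x, y) list(
    x = cos(theta) * x - sin(theta) * y + 150,
    y = sin(theta) * x + cos(theta) * y + 50
  )
  moved <- rot(fx$x, fx$y)
  fx2 <- fx; fx2$x <- moved$x; fx2$y <- moved$y
  sc2 <- derive_saccades(fx2)
  expect_equal(saccade_length(sc2), saccade_length(sc))
  expect_equal(saccade_orientation(sc2), saccade_orientation(sc))
  expect_equal(saccade_slope_angle(sc2) %% 180,
               (saccade_slope_angle(sc) + 30) %% 180)
})

test_that("mean-value features min-max normalize across the dataset", {
  # two images: the one with larger mean duration maps to 1, the other to 0
  fx <- dplyr::bind_rows(
    make_fixations(c(10, 20), c(10, 20), c(0, 500), dur = 400),
    make_fixations(c(10, 20), c(10, 20), c(0, 500), dur = 150,
                   image_id = "img2")
  )
  lb <- tibble::tibble(image_id = c("img1", "img2"), mean_valence = c(4, 5))
  rec <- gaze_recordset(fx, lb, width = 100, height = 100)
  m <- mean_features(rec)
  expect_equal(m$mean_fixation_duration[m$image_id == "img1"], 1)
  expect_equal(m$mean_fixation_duration[m$image_id == "img2"], 0)
  expect_true(all(as.matrix(m[, -1]) >= 0 & as.matrix(m[, -1]) <= 1))

  # identical images degenerate to 0 by convention
  fx2 <- fx
  fx2$t_end_ms <- fx2$t_start_ms + 300
  rec2 <- gaze_recordset(fx2, lb, width = 100, height = 100)
  m2 <- mean_features(rec2)
  expect_true(all(m2$mean_fixation_duration == 0))

  # single image: normalization undefined
  rec1 <- gaze_recordset(fx[fx$image_id == "img1", ], lb[1, ],
                         width = 100, height = 100)
  expect_error(mean_features(rec1), ">= 2 images")

  # naive oracle on generated data
  rec3 <- small_synthetic(seed = 6)
  m3 <- mean_features(rec3)
  sacc <- derive_saccades(rec3)
  raw <- sapply(sort(unique(rec3$fixations$image_id)), function(id) {
    mean(saccade_length(sacc[sacc$image_id == id, ]))
  })
  want <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(m3$mean_saccade_length, unname(want))
})

test_that("feature matrices export with schema and read back", {
  withr::local_dir(withr::local_tempdir())
  rec <- small_synthetic(seed = 9, n_images = c(1, 1, 1), n_observers = 2)
  feats <- extract_features(rec, sigma = 4)
  write_feature_matrix(feats, "feats.csv")
  expect_true(file.exists("feats.csv"))
  expect_true(file.exists("feats.blocks.json"))
  back <- readr::read_csv("feats.csv", show_col_types = FALSE)
  expect_equal(dim(back), dim(feats))
  schema <- jsonlite::read_json("feats.blocks.json", simplifyVector = TRUE)
  expect_equal(schema$size, feature_blocks()$size)
})
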