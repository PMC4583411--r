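test_that("valence labeling partitions the SAM scale into three classes", {
  expect_equal(as.character(label_valence(c(2, 5, 6.5))),
               c("unpleasant", "neutral", "pleasant"))
  # boundaries are neutral
  expect_equal(as.character(label_valence(c(3.8, 5.8))),
               c("neutral", "neutral"))
  # exhaustive and exclusive over a fine grid of the legal range
  grid <- seq(1, 9, by = 0.001)
  cls <- label_valence(grid)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls), c("unpleasant", "neutral", "pleasant"))
  expect_true(all(grid[cls == "unpleasant"] < 3.8))
  expect_true(all(grid[cls == "pleasant"] > 5.8))
  expect_error(label_valence(0.5), "1, 9")
  expect_error(label_valence(9.2), "1, 9")
})

test_that("recordset construction validates fixation invariants", {
  rec <- tiny_recordset()
  expect_s3_class(rec, "gaze_recordset")
  expect_equal(nrow(rec$fixations), 10)

  bad <- make_fixations(10, 10, 100, dur = 50) # below the 100 ms minimum
  expect_error(gaze_recordset(bad, tibble::tibble(image_id = "img1",
                                                  mean_valence = 5)),
               "100 ms.*row", ignore.case = TRUE)
  out <- make_fixations(500, 10, 0) # x out of bounds for a 200 px image
  expect_error(gaze_recordset(out, tibble::tibble(image_id = "img1",
                                                  mean_valence = 5),
                              width = 200, height = 150),
               "x outside")
  # unlabeled image
  expect_error(gaze_recordset(make_fixations(10, 10, 0),
                              tibble::tibble(image_id = "other",
                                             mean_valence = 5),
                              width = 200, height = 150),
               "without a label")
  # missing column reported by name
  expect_error(
    gaze_recordset(make_fixations(10, 10, 0)[, -3],
                   tibble::tibble(image_id = "img1", mean_valence = 5)),
    "x"
  )
})

test_that("fixation tables round-trip through CSV exactly", {
  withr::local_dir(withr::local_tempdir())
  # hand-built and generated recordsets
  for (rec in list(tiny_recordset(), small_synthetic(seed = 3))) {
    write_fixation_table(rec, "fx.csv", "lb.csv")
    back <- read_fixation_table("fx.csv", "lb.csv",
                                width = rec$width, height = rec$height)
    expect_equal(back$fixations, rec$fixations)
    expect_equal(back$labels, rec$labels)
  }
  # empty recordset: header-only fixation file
  empty <- gaze_recordset(
    make_fixations(numeric(), numeric(), numeric()),
    tibble::tibble(image_id = character(), mean_valence = numeric())
  )
  write_fixation_table(empty, "fx0.csv", "lb0.csv")
  expect_equal(length(readLines("fx0.csv")), 1L)
})

test_that("saccades chain consecutive fixations with the inter-fixation gap", {
  fx <- make_fixations(c(0, 30), c(0, 40), c(0, 150), dur = c(100, 150))
  sc <- derive_saccades(fx)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$x_start, 0); expect_equal(sc$y_start, 0)
  expect_equal(sc$x_end, 30); expect_equal(sc$y_end, 40)
  expect_equal(sc$t_start_ms, 100) # end of first fixation
  expect_equal(sc$t_end_ms, 150)   # start of second

  # single fixation and empty input yield no saccades
  expect_equal(nrow(derive_saccades(make_fixations(5, 5, 0))), 0)
  expect_equal(nrow(derive_saccades(make_fixations(numeric(), numeric(),
                                                   numeric()))), 0)

  # chaining property on generated scanpaths: n fixations -> n - 1 saccades,
  # endpoints chain within each scanpath
  rec <- small_synthetic(seed = 7)
  sc <- derive_saccades(rec)
  per_path_fix <- dplyr::count(rec$fixations, image_id, observer_id)
  per_path_sac <- dplyr::count(sc, image_id, observer_id)
  joined <- dplyr::left_join(per_path_fix, per_path_sac,
                             by = c("image_id", "observer_id"))
  joined$n.y[is.na(joined$n.y)] <- 0
  expect_equal(joined$n.y, pmax(0, joined$n.x - 1))
  by_path <- split(sc, paste(sc$image_id, sc$observer_id))
  for (p in by_path) {
    if (nrow(p) > 1) {
      expect_equal(p$x_start[-1], p$x_end[-nrow(p)])
      expect_equal(p$y_start[-1], p$y_end[-nrow(p)])
    }
  }
})
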