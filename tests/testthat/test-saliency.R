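test_that("saliency map peaks at fixations and normalizes to 1", {
  fx <- tibble::tibble(x = 32, y = 24)
  m <- compute_saliency_map(fx, sigma = 4, width = 64, height = 48)
  expect_equal(max(m$full_map), 1)
  peak <- which(m$full_map == 1, arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(25, 33)) # row = y + 1, col = x + 1
  expect_true(all(m$full_map >= 0 & m$full_map <= 1))
  expect_equal(dim(m$coarse_map), c(15, 20))
  expect_true(all(m$coarse_map >= 0 & m$coarse_map <= 1))

  # two well-separated equal fixations: two equal maxima of 1
  fx2 <- tibble::tibble(x = c(10, 54), y = c(10, 38))
  m2 <- compute_saliency_map(fx2, sigma = 2, width = 64, height = 48)
  peaks <- which(abs(m2$full_map - 1) < 1e-9, arr.ind = TRUE)
  expect_equal(nrow(peaks), 2)

  expect_error(compute_saliency_map(fx[0, ], width = 64, height = 48),
               "no fixations")
})

test_that("saliency map matches the brute-force Gaussian sum", {
  set.seed(9)
  fx <- tibble::tibble(x = runif(20, 0, 64), y = runif(20, 0, 48))
  m <- compute_saliency_map(fx, sigma = 4, width = 64, height = 48)
  oracle <- naive_saliency(fx, sigma = 4, width = 64, height = 48)
  # tolerance covers the 4-sigma kernel truncation
  expect_lt(max(abs(m$full_map - oracle)), 2e-3)
})

test_that("fixation histogram uses the 16 x 16 grid with row-major layout", {
  geom <- fixation_grid_geometry(1024, 768)
  expect_equal(geom$n_cells, 256)
  expect_equal(geom$cell_width, 64)
  expect_equal(geom$cell_height, 48)

  h <- fixation_histogram(tibble::tibble(x = 0, y = 0))
  expect_equal(h[1], 1)
  expect_equal(sum(h), 1)
  # cell to the right is index 2; cell below is index 17 (row-major)
  expect_equal(which(fixation_histogram(tibble::tibble(x = 70, y = 0)) > 0), 2L)
  expect_equal(which(fixation_histogram(tibble::tibble(x = 0, y = 50)) > 0), 17L)

  # conservation and brute-force equivalence
  set.seed(4)
  fx <- tibble::tibble(x = runif(200, 0, 1024), y = runif(200, 0, 768))
  counts <- fixation_histogram(fx, normalize = FALSE)
  expect_equal(sum(counts), 200)
  oracle <- numeric(256)
  for (k in seq_len(200)) {
    cell <- (fx$y[k] %/% 48) * 16 + (fx$x[k] %/% 64) + 1
    oracle[cell] <- oracle[cell] + 1
  }
  expect_equal(counts, oracle)
})

test_that("saliency histogram bins map values sampled at fixations", {
  fx <- tibble::tibble(x = 32, y = 24)
  m <- compute_saliency_map(fx, sigma = 4, width = 64, height = 48)
  h <- saliency_histogram(m, fx)
  expect_equal(h[10], 1) # single fixation sits at the map maximum
  expect_equal(saliency_histogram(m, fx[0, ]), numeric(10))

  set.seed(11)
  fx2 <- tibble::tibble(x = runif(30, 0, 64), y = runif(30, 0, 48))
  m2 <- compute_saliency_map(fx2, sigma = 4, width = 64, height = 48)
  vals <- m2$full_map[cbind(floor(fx2$y) + 1, floor(fx2$x) + 1)]
  expect_equal(saliency_histogram(m2, fx2),
               naive_histogram(vals, binning_scheme("s", 10, 0, 1)))
})

test_that("top-10 salient locations follow inhibition of return", {
  # one dominant peak is picked first, at its normalized location
  fx <- tibble::tibble(x = c(40, 40, 10), y = c(30, 30, 5))
  m <- compute_saliency_map(fx, sigma = 2, width = 64, height = 48)
  top <- top10_salient(m)
  expect_length(top, 20)
  expect_equal(top[1], 40 / 64)
  expect_equal(top[2], 30 / 48)
  expect_true(all(top >= 0 & top <= 1))

  # constant map: first pick at (0, 0) by the row-major tie-break
  const <- structure(list(full_map = matrix(1, 48, 64), sigma = 2,
                          width = 64, height = 48),
                     class = "saliency_map")
  expect_equal(top10_salient(const)[1:2], c(0, 0))

  # 10 equal, mutually distant peaks are all recovered as a set
  peaks_xy <- expand.grid(x = c(6, 19, 32, 45, 58), y = c(12, 36))
  mm <- matrix(0, 48, 64)
  mm[cbind(peaks_xy$y + 1, peaks_xy$x + 1)] <- 1
  synth <- structure(list(full_map = mm, sigma = 2, width = 64, height = 48),
                     class = "saliency_map")
  got <- top10_salient(synth, radius = 4)
  got_px <- sort(paste(round(got[seq(1, 20, 2)] * 64),
                       round(got[seq(2, 20, 2)] * 48)))
  want <- sort(paste(peaks_xy$x, peaks_xy$y))
  expect_equal(got_px, want)
})
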