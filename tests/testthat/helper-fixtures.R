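# small hand-built gaze fixtures used across tests

make_fixations <- function(x, y, t_start, dur = 200,
                           image_id = "img1", observer_id = "s1") {
  tibble::tibble(
    image_id = image_id, observer_id = observer_id,
    x = x, y = y, t_start_ms = t_start, t_end_ms = t_start + dur
  )
}

# a tiny valid recordset: 2 images, 2 observers each
tiny_recordset <- function(width = 200, height = 150) {
  fx <- dplyr::bind_rows(
    make_fixations(c(10, 60, 110), c(10, 40, 70), c(0, 300, 700)),
    make_fixations(c(20, 80), c(100, 120), c(0, 400), observer_id = "s2"),
    make_fixations(c(150, 50), c(50, 90), c(0, 500), image_id = "img2"),
    make_fixations(c(90, 130, 40), c(30, 60, 140), c(0, 350, 900),
                   image_id = "img2", observer_id = "s2")
  )
  labels <- tibble::tibble(image_id = c("img1", "img2"),
                           mean_valence = c(2.5, 6.8))
  gaze_recordset(fx, labels, width = width, height = height)
}

# a small synthetic recordset for feature-level tests
small_synthetic <- function(seed = 1, effect = 1,
                            n_images = c(2, 3, 2), n_observers = 4,
                            width = 256, height = 192) {
  generate_gaze(
    synthetic_config(n_images = n_images, n_observers = n_observers,
                     width = width, height = height, effect = effect,
                     spread_px = 40, saccade_px = 60),
    seed = seed
  )
}

# brute-force nearest-center histogram (independent oracle)
naive_histogram <- function(values, scheme, normalize = TRUE) {
  values <- values[!is.na(values)]
  centers <- bin_centers(scheme)
  counts <- numeric(scheme$n_bins)
  for (v in values) {
    i <- which.min(abs(centers - v))
    counts[i] <- counts[i] + 1
  }
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# brute-force per-class Youden J, prevalence weighted (independent oracle)
naive_bookmaker <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  total_j <- 0
  for (c in seq_len(nrow(cm))) {
    pos <- sum(cm[c, ])
    if (pos == 0) next
    tpr <- cm[c, c] / pos
    neg_rows <- setdiff(seq_len(nrow(cm)), c)
    fp <- sum(cm[neg_rows, c])
    neg <- sum(cm[neg_rows, ])
    tnr <- if (neg > 0) (neg - fp) / neg else 0
    total_j <- total_j + (pos / n) * (tpr + tnr - 1)
  }
  total_j
}

# brute-force oracle: untruncated Gaussian sum evaluated at every pixel center
naive_saliency <- function(fixations, sigma, width, height) {
  m <- matrix(0, height, width)
  cx <- floor(fixations$x)
  cy <- floor(fixations$y)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      m[row, col] <- sum(exp(-((col - 1 - cx)^2 + (row - 1 - cy)^2) /
                               (2 * sigma^2)))
    }
  }
  m / max(m)
}
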