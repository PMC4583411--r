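#' Configuration of the synthetic gaze generator
#'
#' The generator emulates the statistical structure that the affective
#' eye-movement literature attributes to valence, at the scale of the
#' reference study: 24 unpleasant / 47 neutral / 24 pleasant images, about 25
#' observers per image, 1024 x 768 px stimuli viewed freely for 5 seconds,
#' fixations of at least 100 ms. Class effects (all scaled by a single
#' `effect` magnitude in \[0, 1\]; 0 is the null mode in which the three
#' classes share one generative process) are:
#'
#' * attentional narrowing: fixations of unpleasant images spread less around
#'   their attractors, pleasant ones more (`spread_delta`);
#' * fixation durations: longer for unpleasant images (log-normal mean shift,
#'   `duration_delta`);
#' * saccade lengths: longer for unpleasant images (`length_delta`);
#' * angular behavior: turning angles between successive saccades are more
#'   concentrated around straight-ahead for unpleasant images
#'   (`turn_sd_delta` scales the wrapped-normal spread of the turning angle).
#'
#' @param n_images Images per class, named or ordered
#'   (unpleasant, neutral, pleasant); default `c(24, 47, 24)`.
#' @param n_observers Observers per image (default 25).
#' @param width,height Stimulus size in pixels (default 1024 x 768).
#' @param window_ms Viewing window in ms (default 5000).
#' @param min_fix_ms Minimum fixation duration in ms (default 100).
#' @param effect Effect magnitude in \[0, 1\]; 0 = null mode (default 1).
#' @param spread_px Baseline (neutral) fixation spread around an attractor,
#'   in pixels.
#' @param duration_meanlog Baseline log-mean of fixation duration (ms).
#' @param saccade_px Baseline median saccade length in pixels.
#' @param turn_sd_rad Baseline SD of the wrapped-normal turning angle
#'   (radians).
#' @param spread_delta,duration_delta,length_delta,turn_sd_delta Relative
#'   per-class effects, each `c(unpleasant, neutral, pleasant)`, applied as
#'   `base * (1 + effect * delta)` (on the log-mean for durations, additive:
#'   `meanlog + effect * delta`).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = c(unpleasant = 24, neutral = 47, pleasant = 24),
                             n_observers = 25,
                             width = 1024, height = 768,
                             window_ms = 5000, min_fix_ms = 100,
                             effect = 1,
                             spread_px = 130,
                             duration_meanlog = log(240),
                             saccade_px = 170,
                             turn_sd_rad = 1.0,
                             spread_delta = c(-0.40, 0, 0.40),
                             duration_delta = c(0.30, 0, -0.15),
                             length_delta = c(0.35, 0, -0.20),
                             turn_sd_delta = c(-0.35, 0, 0.35)) {
  n_images <- as.integer(n_images)
  if (length(n_images) != 3 || any(n_images < 1)) {
    abort("`n_images` must give positive counts for the three classes.")
  }
  if (effect < 0 || effect > 1) abort("`effect` must lie in [0, 1].")
  if (window_ms < min_fix_ms) {
    abort("viewing window shorter than one minimum-duration fixation.")
  }
  if (n_observers < 1 || width <= 0 || height <= 0) {
    abort("observers and image size must be positive.")
  }
  structure(
    list(
      n_images = stats::setNames(n_images, valence_levels),
      n_observers = as.integer(n_observers),
      width = width, height = height,
      window_ms = window_ms, min_fix_ms = min_fix_ms,
      effect = effect,
      spread_px = spread_px, duration_meanlog = duration_meanlog,
      saccade_px = saccade_px, turn_sd_rad = turn_sd_rad,
      spread_delta = spread_delta, duration_delta = duration_delta,
      length_delta = length_delta, turn_sd_delta = turn_sd_delta
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %s images, %d observers, %g x %g px, %g ms window, effect %.2f\n",
    paste(x$n_images, collapse = "/"), x$n_observers, x$width, x$height,
    x$window_ms, x$effect
  ))
  invisible(x)
}

# per-class generative parameters under the configured effect magnitude
class_params <- function(config) {
  e <- config$effect
  tibble::tibble(
    valence_class = valence_levels,
    spread = config$spread_px * (1 + e * config$spread_delta),
    meanlog_dur = config$duration_meanlog + e * config$duration_delta,
    saccade = config$saccade_px * (1 + e * config$length_delta),
    turn_sd = config$turn_sd_rad * (1 + e * config$turn_sd_delta)
  )
}

#' Generate a labeled synthetic gaze recordset
#'
#' Per image: 2-4 attractor points are placed in the central region; each
#' observer's scanpath starts near an attractor and alternates between
#' persistent moves (direction = previous direction plus a wrapped-normal
#' turning angle, length log-normal around the class's saccade scale) and
#' relocations toward another attractor (probability 0.35), with fixation
#' durations drawn log-normally (floored at the minimum duration) and 20-60
#' ms inter-fixation gaps, until the viewing window is exhausted. Locations
#' are clipped to the image bounds. Each image receives a mean valence drawn
#' uniformly within its class's band of the 1-9 scale, so [label_valence()]
#' reproduces the class. Byte-identical output under the same seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A [gaze_recordset()].
#' @examples
#' rec <- generate_gaze(synthetic_config(n_images = c(2, 3, 2), n_observers = 4),
#'                      seed = 42)
#' rec
#' @export
generate_gaze <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  pars <- class_params(config)
  rating_band <- list(unpleasant = c(1.5, 3.79), neutral = c(3.8, 5.8),
                      pleasant = c(5.81, 8.5))
  with_seed(seed, {
    img_class <- rep(valence_levels, config$n_images)
    n_img <- length(img_class)
    img_ids <- sprintf("img%03d", seq_len(n_img))
    labels <- tibble::tibble(
      image_id = img_ids,
      mean_valence = vapply(img_class, function(cl) {
        stats::runif(1, rating_band[[cl]][1], rating_band[[cl]][2])
      }, numeric(1), USE.NAMES = FALSE),
      valence_class = factor(img_class, levels = valence_levels)
    )
    fixations <- purrr::map2(img_ids, img_class, function(id, cl) {
      p <- pars[pars$valence_class == cl, ]
      n_attr <- sample(2:4, 1)
      attractors <- cbind(
        stats::runif(n_attr, 0.2 * config$width, 0.8 * config$width),
        stats::runif(n_attr, 0.2 * config$height, 0.8 * config$height)
      )
      purrr::map(seq_len(config$n_observers), function(obs) {
        simulate_scanpath(id, sprintf("obs%02d", obs), attractors, p, config)
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
    gaze_recordset(fixations, labels,
                   width = config$width, height = config$height)
  })
}

# one observer's scanpath as a fixation tibble
simulate_scanpath <- function(image_id, observer_id, attractors, p, config) {
  clip <- function(x, hi) pmin(pmax(x, 0), hi - 1e-6)
  a <- attractors[sample.int(nrow(attractors), 1), ]
  loc <- c(clip(a[1] + stats::rnorm(1, 0, p$spread), config$width),
           clip(a[2] + stats::rnorm(1, 0, p$spread), config$height))
  dir <- stats::runif(1, 0, 2 * pi)
  t <- 0
  xs <- numeric(); ys <- numeric(); t0 <- numeric(); t1 <- numeric()
  repeat {
    dur <- max(config$min_fix_ms,
               stats::rlnorm(1, p$meanlog_dur, 0.4))
    if (t + dur > config$window_ms) break
    xs <- c(xs, loc[1]); ys <- c(ys, loc[2])
    t0 <- c(t0, t); t1 <- c(t1, t + dur)
    t <- t + dur + stats::runif(1, 20, 60)
    if (stats::runif(1) < 0.35) {
      a <- attractors[sample.int(nrow(attractors), 1), ]
      target <- c(clip(a[1] + stats::rnorm(1, 0, p$spread), config$width),
                  clip(a[2] + stats::rnorm(1, 0, p$spread), config$height))
      dir <- atan2(target[2] - loc[2], target[1] - loc[1])
      loc <- target
    } else {
      dir <- dir + stats::rnorm(1, 0, p$turn_sd)
      len <- stats::rlnorm(1, log(p$saccade), 0.5)
      prop <- loc + len * c(cos(dir), sin(dir))
      # containment: a move escaping the attractor's neighborhood (radius
      # scaled by the class spread) is redirected back toward it, so spatial
      # spread stays governed by the spread parameter even when the class
      # makes long saccades
      if (sqrt(sum((prop - a)^2)) > 2.5 * p$spread) {
        dir <- atan2(a[2] - loc[2], a[1] - loc[1]) + stats::rnorm(1, 0, 0.3)
        prop <- loc + len * c(cos(dir), sin(dir))
      }
      loc <- c(clip(prop[1], config$width), clip(prop[2], config$height))
    }
  }
  if (length(xs) == 0) {
    # degenerate draw: keep one minimum-duration fixation so the scanpath
    # stays within the window yet non-empty
    xs <- loc[1]; ys <- loc[2]; t0 <- 0; t1 <- config$min_fix_ms
  }
  tibble::tibble(
    image_id = image_id, observer_id = observer_id,
    x = xs, y = ys, t_start_ms = t0, t_end_ms = t1
  )
}

#' Permute class labels for null calibration
#'
#' Returns the same gaze data with the per-image labels (class and rating,
#' moved together) randomly permuted across images. A classifier evaluated on
#' the permuted recordset should score at chance level (Bookmaker near 0).
#'
#' @param recordset A [gaze_recordset()].
#' @param seed Integer seed.
#' @return A [gaze_recordset()] with permuted labels; the label multiset is
#'   preserved.
#' @export
permute_valence_labels <- function(recordset, seed = 1) {
  stopifnot(inherits(recordset, "gaze_recordset"))
  lb <- recordset$labels
  perm <- with_seed(seed, sample.int(nrow(lb)))
  lb$mean_valence <- lb$mean_valence[perm]
  lb$valence_class <- lb$valence_class[perm]
  gaze_recordset(recordset$fixations, lb,
                 width = recordset$width, height = recordset$height)
}
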