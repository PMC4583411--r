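#' Extract the 872-dimensional feature matrix of a recordset
#'
#' For each image, pools the fixations of all observers (and the saccades
#' derived per observer) and computes the ten feature blocks described in
#' [feature_blocks()]: the coarse 15 x 20 saliency map (flattened row-major),
#' the ten top salient locations, the 16 x 16 spatial fixation histogram, the
#' saliency-value histogram and the six property histograms. Pooling is
#' order-invariant: permuting observers leaves the features unchanged.
#'
#' @param recordset A [gaze_recordset()].
#' @param schemes Binning schemes, as from [default_binning_schemes()].
#' @param sigma Saliency-map Gaussian width in pixels.
#' @param normalize Normalize histogram blocks to probability mass
#'   (default `TRUE`); raw counts when `FALSE`.
#' @return Tibble with one row per image: `image_id` followed by the 872
#'   feature columns named as in [feature_dim_names()]. The block schema is
#'   attached as attribute `"blocks"`.
#' @examples
#' rec <- generate_gaze(synthetic_config(n_images = c(2, 2, 2), n_observers = 3,
#'                                       width = 160, height = 120), seed = 1)
#' feats <- extract_features(rec, sigma = 4)
#' dim(feats) # images x (1 + 872)
#' @export
extract_features <- function(recordset,
                             schemes = default_binning_schemes(recordset$width,
                                                               recordset$height),
                             sigma = 10, normalize = TRUE) {
  stopifnot(inherits(recordset, "gaze_recordset"))
  if (nrow(recordset$fixations) == 0) {
    abort("cannot extract features: the recordset holds no fixations.")
  }
  ids <- sort(unique(recordset$fixations$image_id))
  sacc_all <- derive_saccades(recordset$fixations)
  rows <- purrr::map(ids, function(id) {
    fx <- recordset$fixations[recordset$fixations$image_id == id, ]
    sc <- sacc_all[sacc_all$image_id == id, ]
    extract_image_features(fx, sc, recordset$width, recordset$height,
                           schemes = schemes, sigma = sigma,
                           normalize = normalize)
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- feature_dim_names()
  out <- dplyr::bind_cols(tibble::tibble(image_id = ids), out)
  attr(out, "blocks") <- feature_blocks()
  out
}

# one image's 872-vector from pooled fixations and per-observer saccades
extract_image_features <- function(fixations, saccades, width, height,
                                   schemes, sigma = 10, normalize = TRUE) {
  if (nrow(fixations) == 0) abort("image without fixations.")
  map <- compute_saliency_map(fixations, sigma = sigma,
                              width = width, height = height)
  c(
    as.vector(t(map$coarse_map)),                     # 300, row-major
    top10_salient(map),                               # 20
    fixation_histogram(fixations, width, height,
                       normalize = normalize),        # 256
    saliency_histogram(map, fixations,
                       normalize = normalize),        # 10
    fixation_duration_histogram(fixations, schemes$fixation_duration,
                                normalize),           # 60
    saccade_duration_histogram(saccades, schemes$saccade_duration,
                               normalize),            # 60
    saccade_slope_histogram(saccades, schemes$saccade_slope,
                            normalize),               # 30
    saccade_length_histogram(saccades, schemes$saccade_length,
                             normalize),              # 50
    saccade_velocity_histogram(saccades, schemes$saccade_velocity,
                               normalize),            # 50
    saccade_orientation_histogram(saccades, schemes$saccade_orientation,
                                  normalize)          # 36
  )
}

#' Normalized mean-value features
#'
#' The traditional behavioral representation: for each image, the mean of
#' each gaze property (fixation duration, saccade duration, saccade length,
#' saccade slope, saccade velocity, saccade orientation) over all observers'
#' events, min-max normalized across the dataset's images to \[0, 1\]. The
#' normalization is a dataset-level operation, so at least two images are
#' required; a property that is constant across images maps to 0 by
#' convention, as does a property with no defined events on an image.
#'
#' @param recordset A [gaze_recordset()] with at least two images.
#' @return Tibble with one row per image: `image_id` plus columns
#'   `mean_fixation_duration`, `mean_saccade_duration`, `mean_saccade_length`,
#'   `mean_saccade_slope`, `mean_saccade_velocity`,
#'   `mean_saccade_orientation`, each in \[0, 1\].
#' @export
mean_features <- function(recordset) {
  stopifnot(inherits(recordset, "gaze_recordset"))
  ids <- sort(unique(recordset$fixations$image_id))
  if (length(ids) < 2) {
    abort("mean features need >= 2 images (min-max normalization is across images).")
  }
  sacc_all <- derive_saccades(recordset$fixations)
  raw <- purrr::map(ids, function(id) {
    fx <- recordset$fixations[recordset$fixations$image_id == id, ]
    sc <- sacc_all[sacc_all$image_id == id, ]
    c(
      mean_fixation_duration = mean(fixation_duration(fx)),
      mean_saccade_duration = mean_or_na(saccade_duration(sc)),
      mean_saccade_length = mean_or_na(saccade_length(sc)),
      mean_saccade_slope = mean_or_na(saccade_slope_angle(sc)),
      mean_saccade_velocity = mean_or_na(saccade_velocity(sc)),
      mean_saccade_orientation = mean_or_na(saccade_orientation(sc))
    )
  })
  mat <- do.call(rbind, raw)
  norm <- apply(mat, 2, function(v) {
    v[is.na(v)] <- 0
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  })
  dplyr::bind_cols(tibble::tibble(image_id = ids),
                   tibble::as_tibble(as.data.frame(norm)))
}

mean_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v)) mean(v) else NA_real_
}

#' Export a feature matrix with its block schema
#'
#' Writes the feature tibble as CSV (one row per image, block-prefixed
#' headers) and the block schema as JSON next to it.
#'
#' @param features Output of [extract_features()].
#' @param path CSV destination.
#' @param schema_path JSON destination for the block schema (default:
#'   `path` with extension `.blocks.json`).
#' @return `features`, invisibly.
#' @export
write_feature_matrix <- function(features, path,
                                 schema_path = sub("\\.csv$", ".blocks.json", path)) {
  readr::write_csv(features, path)
  jsonlite::write_json(feature_blocks(), schema_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(features)
}

#' Export a saliency map
#'
#' Writes the full-resolution map as a plain numeric matrix CSV (one row per
#' pixel row), or as an 8-bit grayscale PNG when the `png` package is
#' available.
#'
#' @param map A [compute_saliency_map()] result.
#' @param path Destination file.
#' @param format `"csv"` (default) or `"png"`.
#' @return `map`, invisibly.
#' @export
write_saliency_map <- function(map, path, format = c("csv", "png")) {
  stopifnot(inherits(map, "saliency_map"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(map$full_map, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("PNG export needs the `png` package; use format = \"csv\".")
    }
    png::writePNG(map$full_map, target = path)
  }
  invisible(map)
}
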