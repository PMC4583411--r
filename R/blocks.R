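#' Feature block schema
#'
#' The full feature vector concatenates ten named blocks in a fixed order.
#' The blocks and their dimensionalities are: coarse saliency map (300 =
#' 15 x 20 cells), top-10 salient locations (20 = ten normalized x,y pairs),
#' spatial fixation histogram (256 = 16 x 16 grid), saliency-value histogram
#' (10), fixation-duration histogram (60), saccade-duration histogram (60),
#' saccade-slope histogram (30), saccade-length histogram (50),
#' saccade-velocity histogram (50) and saccade-orientation histogram (36),
#' for a total of 872 dimensions.
#'
#' @return A tibble with one row per block and columns `block` (name),
#'   `size` (number of dimensions), `start` and `end` (1-based column
#'   positions within the 872-dimensional vector).
#' @examples
#' feature_blocks()
#' sum(feature_blocks()$size) # 872
#' @export
feature_blocks <- function() {
  blocks <- tibble::tibble(
    block = c(
      "saliency_map", "top10_salient", "fixation_histogram",
      "saliency_histogram", "fixation_duration_hist", "saccade_duration_hist",
      "saccade_slope_hist", "saccade_length_hist", "saccade_velocity_hist",
      "saccade_orientation_hist"
    ),
    size = c(300L, 20L, 256L, 10L, 60L, 60L, 30L, 50L, 50L, 36L)
  )
  blocks$end <- cumsum(blocks$size)
  blocks$start <- blocks$end - blocks$size + 1L
  blocks[, c("block", "size", "start", "end")]
}

#' Total dimensionality of the concatenated feature vector
#' @return Integer, 872.
#' @export
n_feature_dims <- function() sum(feature_blocks()$size)

#' Column names for the concatenated feature vector
#'
#' Block-prefixed, zero-padded names such as `saliency_map_001`.
#'
#' @return Character vector of length 872.
#' @export
feature_dim_names <- function() {
  blocks <- feature_blocks()
  unlist(purrr::map2(blocks$block, blocks$size, function(b, k) {
    sprintf("%s_%03d", b, seq_len(k))
  }), use.names = FALSE)
}

#' Construct a histogram binning scheme
#'
#' A scheme places `n_bins` bin centers uniformly over
#' `[range_low, range_high]`; values are assigned to the nearest center and
#' values outside the range are clipped into the end bins.
#'
#' @param property Name of the gaze property the scheme bins.
#' @param n_bins Number of bins (>= 1).
#' @param range_low,range_high Range covered by the bin centers, in the
#'   property's units; `range_high` must exceed `range_low`.
#' @return An object of class `binning_scheme`.
#' @examples
#' binning_scheme("saccade_length", 50, 0, 1280)
#' @export
binning_scheme <- function(property, n_bins, range_low, range_high) {
  stopifnot(is.character(property), length(property) == 1L)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) {
    abort("`n_bins` must be a positive integer.")
  }
  if (!is.finite(range_low) || !is.finite(range_high) ||
      range_high <= range_low) {
    abort("`range_high` must be strictly greater than `range_low`.")
  }
  structure(
    list(
      property = property, n_bins = n_bins,
      range_low = as.numeric(range_low), range_high = as.numeric(range_high)
    ),
    class = "binning_scheme"
  )
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf(
    "<binning_scheme> %s: %d bins, centers over [%g, %g]\n",
    x$property, x$n_bins, x$range_low, x$range_high
  ))
  invisible(x)
}

#' Bin centers of a scheme
#' @param scheme A [binning_scheme()].
#' @return Numeric vector of `n_bins` uniformly spaced centers.
#' @export
bin_centers <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (scheme$n_bins == 1L) {
    return((scheme$range_low + scheme$range_high) / 2)
  }
  seq(scheme$range_low, scheme$range_high, length.out = scheme$n_bins)
}

#' Default binning schemes for the histogram features
#'
#' Ranges are dataset-global conventions, frozen so that feature vectors of
#' different images (and different datasets) are comparable: fixation
#' durations 100-2000 ms, saccade durations 0-2000 ms, saccade lengths 0 to
#' the image diagonal, saccade velocities 0-10 px/ms, saccade slopes 0-180
#' degrees and saccade orientations 0-180 degrees (the angle between
#' successive saccades is computed through an arccosine and therefore lives
#' in [0, 180]). A 0-360 degree orientation convention, which bins the signed
#' turning angle instead, is available via `orientation_range`.
#'
#' @param width,height Image size in pixels; bounds the saccade-length range
#'   by the diagonal.
#' @param orientation_range Either 180 (default, arccosine angle between
#'   saccades) or 360 (signed turning angle folded into [0, 360)).
#' @return Named list of [binning_scheme()] objects with elements
#'   `fixation_duration`, `saccade_duration`, `saccade_slope`,
#'   `saccade_length`, `saccade_velocity`, `saccade_orientation`.
#' @examples
#' schemes <- default_binning_schemes()
#' schemes$saccade_slope
#' @export
default_binning_schemes <- function(width = 1024, height = 768,
                                    orientation_range = c(180, 360)) {
  orientation_range <- match.arg(as.character(orientation_range[1]),
                                 c("180", "360"))
  diag_px <- sqrt(width^2 + height^2)
  list(
    fixation_duration = binning_scheme("fixation_duration", 60, 100, 2000),
    saccade_duration = binning_scheme("saccade_duration", 60, 0, 2000),
    saccade_slope = binning_scheme("saccade_slope", 30, 0, 180),
    saccade_length = binning_scheme("saccade_length", 50, 0, diag_px),
    saccade_velocity = binning_scheme("saccade_velocity", 50, 0, 10),
    saccade_orientation = binning_scheme(
      "saccade_orientation", 36, 0, as.numeric(orientation_range)
    )
  )
}
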