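#' Build a nearest-center histogram under a binning scheme
#'
#' Values are assigned to the nearest of the scheme's uniformly spaced bin
#' centers; values outside `[range_low, range_high]` are clipped into the end
#' bins, so no observation is dropped for being out of range. `NA` values
#' (undefined events such as zero-displacement slopes) are excluded before
#' binning. By default counts are normalized to a probability mass function;
#' an empty input yields the all-zero vector.
#'
#' @param values Numeric vector of property values; `NA`s are dropped.
#' @param scheme A [binning_scheme()].
#' @param normalize Divide counts by their total (default `TRUE`); with no
#'   surviving values the vector is all zeros either way.
#' @return Numeric vector of length `scheme$n_bins`.
#' @examples
#' sch <- binning_scheme("toy", 5, 0, 10)
#' build_histogram(c(0, 10, 10), sch)
#' @export
build_histogram <- function(values, scheme, normalize = TRUE) {
  stopifnot(inherits(scheme, "binning_scheme"))
  values <- values[!is.na(values)]
  counts <- numeric(scheme$n_bins)
  if (length(values)) {
    if (scheme$n_bins == 1L) {
      idx <- rep(1L, length(values))
    } else {
      step <- (scheme$range_high - scheme$range_low) / (scheme$n_bins - 1L)
      # nearest center; values exactly half-way between two centers go to
      # the lower one
      idx <- ceiling((values - scheme$range_low) / step - 0.5) + 1L
      idx <- pmin(pmax(idx, 1L), scheme$n_bins)
    }
    tab <- tabulate(idx, nbins = scheme$n_bins)
    counts <- as.numeric(tab)
    if (normalize) counts <- counts / sum(counts)
  }
  counts
}

#' Histogram features of one image's pooled gaze events
#'
#' Each of the six property histograms pools the events of all observers of
#' one image and delegates to [build_histogram()] with the property's scheme:
#' fixation duration (60 bins), saccade duration (60), saccade slope (30 bins,
#' a 6-degree quantization of 0-180), saccade length (50), saccade velocity
#' (50) and saccade orientation (36 bins over 0-180, i.e. 5 degrees per bin
#' under the arccosine convention). Undefined events are excluded from their
#' histogram only.
#'
#' @param fixations,saccades Pooled event tables of a single image.
#' @param scheme A [binning_scheme()] for the property (defaults to the
#'   matching entry of [default_binning_schemes()]).
#' @param normalize Passed to [build_histogram()].
#' @return Numeric histogram vector.
#' @name property_histograms
NULL

#' @rdname property_histograms
#' @export
fixation_duration_histogram <- function(fixations,
                                        scheme = default_binning_schemes()$fixation_duration,
                                        normalize = TRUE) {
  build_histogram(fixation_duration(fixations), scheme, normalize)
}

#' @rdname property_histograms
#' @export
saccade_duration_histogram <- function(saccades,
                                       scheme = default_binning_schemes()$saccade_duration,
                                       normalize = TRUE) {
  build_histogram(saccade_duration(saccades), scheme, normalize)
}

#' @rdname property_histograms
#' @export
saccade_slope_histogram <- function(saccades,
                                    scheme = default_binning_schemes()$saccade_slope,
                                    normalize = TRUE) {
  build_histogram(saccade_slope_angle(saccades), scheme, normalize)
}

#' @rdname property_histograms
#' @export
saccade_length_histogram <- function(saccades,
                                     scheme = default_binning_schemes()$saccade_length,
                                     normalize = TRUE) {
  build_histogram(saccade_length(saccades), scheme, normalize)
}

#' @rdname property_histograms
#' @export
saccade_velocity_histogram <- function(saccades,
                                       scheme = default_binning_schemes()$saccade_velocity,
                                       normalize = TRUE) {
  build_histogram(saccade_velocity(saccades), scheme, normalize)
}

#' @rdname property_histograms
#' @param signed Use the signed 0-360 turning-angle convention (pair with a
#'   0-360 scheme from `default_binning_schemes(orientation_range = 360)`).
#' @export
saccade_orientation_histogram <- function(saccades,
                                          scheme = default_binning_schemes()$saccade_orientation,
                                          normalize = TRUE, signed = FALSE) {
  build_histogram(saccade_orientation(saccades, signed = signed),
                  scheme, normalize)
}
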