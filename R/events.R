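#' Per-event gaze metrics
#'
#' Vectorized metrics over fixation and saccade tables. Events whose metric is
#' undefined (a zero-displacement saccade has no slope; a zero-duration
#' saccade has no velocity; an orientation needs two non-degenerate saccades)
#' return `NA` and are excluded from the corresponding histograms downstream,
#' not from the scanpath itself.
#'
#' @param fixations,saccades Event tables as produced by the gaze data model
#'   ([derive_saccades()] for saccades).
#' @return Numeric vector, one value per event (per consecutive saccade pair
#'   for `saccade_orientation`, which returns `n - 1` values for `n`
#'   saccades of one scanpath).
#' @name event_metrics
NULL

#' @rdname event_metrics
#' @details `fixation_duration()`: dwell time `t_end_ms - t_start_ms` in ms.
#' @export
fixation_duration <- function(fixations) {
  fixations$t_end_ms - fixations$t_start_ms
}

#' @rdname event_metrics
#' @details `saccade_length()`: Euclidean displacement in pixels.
#' @export
saccade_length <- function(saccades) {
  sqrt((saccades$x_end - saccades$x_start)^2 +
         (saccades$y_end - saccades$y_start)^2)
}

#' @rdname event_metrics
#' @details `saccade_duration()`: `t_end_ms - t_start_ms` in ms (the
#'   inter-fixation gap).
#' @export
saccade_duration <- function(saccades) {
  saccades$t_end_ms - saccades$t_start_ms
}

#' @rdname event_metrics
#' @details `saccade_slope_angle()`: undirected angle of the line connecting
#'   the two fixations, folded into \[0, 180) degrees; horizontal movement is
#'   0, vertical 90. `NA` for zero displacement.
#' @export
saccade_slope_angle <- function(saccades) {
  dx <- saccades$x_end - saccades$x_start
  dy <- saccades$y_end - saccades$y_start
  ang <- atan2(dy, dx) * 180 / pi
  ang <- ang %% 180
  ang[dx == 0 & dy == 0] <- NA_real_
  ang
}

#' @rdname event_metrics
#' @details `saccade_velocity()`: length over duration in px/ms; `NA` for
#'   zero duration.
#' @export
saccade_velocity <- function(saccades) {
  len <- saccade_length(saccades)
  dur <- saccade_duration(saccades)
  out <- len / dur
  out[dur <= 0] <- NA_real_
  out
}

#' @rdname event_metrics
#' @details `saccade_orientation()`: angle between successive saccades of the
#'   same scanpath, `acos` of the cosine similarity of their displacement
#'   vectors, in \[0, 180\] degrees. With `signed = TRUE` the signed turning
#'   angle folded into \[0, 360) is returned instead. `NA` when either
#'   displacement is zero.
#' @param signed Return the signed turning angle in \[0, 360) instead of the
#'   arccosine angle in \[0, 180\].
#' @export
saccade_orientation <- function(saccades, signed = FALSE) {
  if (nrow(saccades) == 0) return(numeric())
  grp <- paste(saccades$image_id %||% "", saccades$observer_id %||% "",
               sep = "\r")
  dx <- saccades$x_end - saccades$x_start
  dy <- saccades$y_end - saccades$y_start
  n <- nrow(saccades)
  if (n < 2) return(numeric())
  i <- 2:n
  prev <- i - 1L
  same <- grp[i] == grp[prev]
  dot <- dx[i] * dx[prev] + dy[i] * dy[prev]
  cross <- dx[prev] * dy[i] - dy[prev] * dx[i]
  n1 <- sqrt(dx[i]^2 + dy[i]^2)
  n0 <- sqrt(dx[prev]^2 + dy[prev]^2)
  if (signed) {
    ang <- (atan2(cross, dot) * 180 / pi) %% 360
  } else {
    cosv <- pmin(1, pmax(-1, dot / (n1 * n0)))
    ang <- acos(cosv) * 180 / pi
  }
  ang[n1 == 0 | n0 == 0] <- NA_real_
  ang[same]
}
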