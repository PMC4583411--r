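valence_levels <- c("unpleasant", "neutral", "pleasant")

# neutral band of the 1-9 SAM mean-valence scale; boundaries inclusive
neutral_low <- 3.8
neutral_high <- 5.8

fixation_cols <- c("image_id", "observer_id", "x", "y", "t_start_ms", "t_end_ms")

#' Assign a valence class from a mean SAM rating
#'
#' Images rated on the 1-9 Self-Assessment Manikin (SAM) valence scale are
#' classed as `neutral` when the mean rating lies in \[3.8, 5.8\] (boundaries
#' inclusive), `unpleasant` below and `pleasant` above. The three classes
#' partition \[1, 9\] exhaustively and exclusively.
#'
#' @param mean_valence Numeric vector of mean ratings in \[1, 9\].
#' @return Factor with levels `unpleasant`, `neutral`, `pleasant`.
#' @examples
#' label_valence(c(2, 5, 6.5))
#' @export
label_valence <- function(mean_valence) {
  if (!is.numeric(mean_valence)) {
    abort("`mean_valence` must be numeric.")
  }
  bad <- !is.na(mean_valence) & (mean_valence < 1 | mean_valence > 9)
  if (any(bad)) {
    abort(sprintf(
      "mean valence must lie in [1, 9]; offending value(s): %s",
      paste(utils::head(mean_valence[bad], 5), collapse = ", ")
    ))
  }
  cls <- ifelse(mean_valence < neutral_low, "unpleasant",
                ifelse(mean_valence > neutral_high, "pleasant", "neutral"))
  factor(cls, levels = valence_levels)
}

#' Construct a gaze recordset
#'
#' A recordset bundles the fixation table of one experiment (all observers,
#' all images) with per-image valence labels and the common stimulus size.
#' Fixations are the elementary gaze events: a dwell at pixel location
#' `(x, y)` from `t_start_ms` to `t_end_ms`, lasting at least 100 ms.
#'
#' @param fixations Data frame with columns `image_id`, `observer_id`, `x`,
#'   `y`, `t_start_ms`, `t_end_ms`.
#' @param labels Data frame with columns `image_id`, `mean_valence` and
#'   optionally `valence_class`; the class is derived with [label_valence()]
#'   when absent.
#' @param width,height Stimulus size in pixels (all images share it).
#' @return An object of class `gaze_recordset`: a list with elements
#'   `fixations` (tibble, ordered by image, observer, onset), `labels`
#'   (tibble) and `width`/`height`.
#' @export
gaze_recordset <- function(fixations, labels, width = 1024, height = 768) {
  if (width <= 0 || height <= 0) abort("image width/height must be positive.")
  fixations <- as_tibble(fixations)
  labels <- as_tibble(labels)
  missing_fix <- setdiff(fixation_cols, names(fixations))
  if (length(missing_fix)) {
    abort(sprintf("fixation table lacks column(s): %s",
                  paste(missing_fix, collapse = ", ")))
  }
  if (!all(c("image_id", "mean_valence") %in% names(labels))) {
    abort("label table needs columns `image_id` and `mean_valence`.")
  }
  fixations$image_id <- as.character(fixations$image_id)
  fixations$observer_id <- as.character(fixations$observer_id)
  labels$image_id <- as.character(labels$image_id)
  if (!"valence_class" %in% names(labels)) {
    labels$valence_class <- label_valence(labels$mean_valence)
  } else {
    labels$valence_class <- factor(as.character(labels$valence_class),
                                   levels = valence_levels)
  }
  labels <- dplyr::arrange(labels[, c("image_id", "mean_valence", "valence_class")],
                           image_id)

  problems <- validate_fixations(fixations, width, height)
  unlabeled <- setdiff(unique(fixations$image_id), labels$image_id)
  if (length(unlabeled)) {
    problems <- c(problems, sprintf("image_id without a label: %s",
                                    paste(unlabeled, collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste(c("invalid gaze recordset:", problems), collapse = "\n  "))
  }
  fixations <- dplyr::arrange(fixations[, fixation_cols],
                              image_id, observer_id, t_start_ms)
  structure(
    list(fixations = fixations, labels = labels,
         width = as.numeric(width), height = as.numeric(height)),
    class = "gaze_recordset"
  )
}

# returns character vector of violation messages with 1-based row numbers
validate_fixations <- function(fixations, width, height) {
  problems <- character()
  fail <- function(mask, what) {
    rows <- which(mask)
    if (length(rows)) {
      sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
              paste(utils::head(rows, 10), collapse = ", "))
    } else character()
  }
  with(fixations, {
    c(
      fail(!is.finite(x) | !is.finite(y) |
             !is.finite(t_start_ms) | !is.finite(t_end_ms),
           "non-finite coordinate or timestamp"),
      # 1e-6 ms slack absorbs floating-point rounding of the timestamps
      fail(is.finite(t_end_ms) & is.finite(t_start_ms) &
             t_end_ms - t_start_ms < 100 - 1e-6,
           "fixation shorter than the 100 ms minimum"),
      fail(is.finite(x) & (x < 0 | x >= width),
           sprintf("x outside [0, %g)", width)),
      fail(is.finite(y) & (y < 0 | y >= height),
           sprintf("y outside [0, %g)", height))
    )
  }) -> problems
  # overlapping fixation intervals within a scanpath
  overlaps <- fixations %>%
    dplyr::group_by(image_id, observer_id) %>%
    dplyr::arrange(t_start_ms, .by_group = TRUE) %>%
    dplyr::summarise(
      bad = any(t_start_ms[-1] < t_end_ms[-dplyr::n()]) && dplyr::n() > 1,
      .groups = "drop"
    )
  if (any(overlaps$bad)) {
    problems <- c(problems, sprintf(
      "overlapping fixation intervals in scanpath(s): %s",
      paste(utils::head(
        paste(overlaps$image_id[overlaps$bad],
              overlaps$observer_id[overlaps$bad], sep = "/"), 5
      ), collapse = ", ")
    ))
  }
  problems
}

#' @export
print.gaze_recordset <- function(x, ...) {
  cat(sprintf(
    "<gaze_recordset> %d fixations, %d images, %d observers, %g x %g px\n",
    nrow(x$fixations), dplyr::n_distinct(x$fixations$image_id),
    dplyr::n_distinct(x$fixations$observer_id), x$width, x$height
  ))
  print(dplyr::count(x$labels, valence_class, .drop = FALSE))
  invisible(x)
}

#' Read a fixation table and its label table
#'
#' Reads the package's plain-CSV gaze dialect: a fixation table with header
#' `image_id,observer_id,x,y,t_start_ms,t_end_ms` and a companion label table
#' with header `image_id,mean_valence[,valence_class]`. Rows violating the
#' fixation invariants (duration >= 100 ms, location within the image) are
#' reported by row number and the read fails.
#'
#' @param path Path of the fixation CSV.
#' @param labels_path Path of the label CSV.
#' @param width,height Stimulus size in pixels.
#' @return A [gaze_recordset()].
#' @seealso [write_fixation_table()]
#' @export
read_fixation_table <- function(path, labels_path, width = 1024, height = 768) {
  fixations <- readr::read_csv(
    path,
    col_types = readr::cols(
      image_id = readr::col_character(),
      observer_id = readr::col_character(),
      x = readr::col_double(), y = readr::col_double(),
      t_start_ms = readr::col_double(), t_end_ms = readr::col_double()
    )
  )
  labels <- readr::read_csv(labels_path, col_types = readr::cols(
    image_id = readr::col_character()
  ))
  gaze_recordset(fixations, labels, width = width, height = height)
}

#' Write a gaze recordset to the fixation/label CSV dialect
#'
#' Emits exactly the dialect [read_fixation_table()] accepts, with a
#' deterministic row order (image, observer, fixation onset) so identical
#' recordsets yield byte-identical files.
#'
#' @param recordset A [gaze_recordset()].
#' @param path Destination of the fixation CSV.
#' @param labels_path Destination of the label CSV.
#' @return `recordset`, invisibly.
#' @export
write_fixation_table <- function(recordset, path, labels_path) {
  stopifnot(inherits(recordset, "gaze_recordset"))
  fx <- dplyr::arrange(recordset$fixations, image_id, observer_id, t_start_ms)
  readr::write_csv(fx, path)
  lb <- recordset$labels
  lb$valence_class <- as.character(lb$valence_class)
  readr::write_csv(lb, labels_path)
  invisible(recordset)
}

#' Derive saccades from fixation sequences
#'
#' A saccade is approximated as the straight jump between two consecutive
#' fixations of the same observer on the same image: it starts at the
#' location of fixation *i* when that fixation ends and lands at the location
#' of fixation *i+1* when it starts. A scanpath of *n* fixations yields
#' *n - 1* saccades; scanpaths with fewer than two fixations yield none.
#'
#' @param fixations Data frame of fixations (columns `image_id`,
#'   `observer_id`, `x`, `y`, `t_start_ms`, `t_end_ms`) or a
#'   [gaze_recordset()].
#' @return Tibble with columns `image_id`, `observer_id`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `t_start_ms`, `t_end_ms`.
#' @examples
#' fx <- tibble::tibble(
#'   image_id = "img1", observer_id = "s1",
#'   x = c(0, 30), y = c(0, 40), t_start_ms = c(0, 150), t_end_ms = c(100, 300)
#' )
#' derive_saccades(fx)
#' @export
derive_saccades <- function(fixations) {
  if (inherits(fixations, "gaze_recordset")) fixations <- fixations$fixations
  fixations <- as_tibble(fixations)
  empty <- tibble::tibble(
    image_id = character(), observer_id = character(),
    x_start = numeric(), y_start = numeric(),
    x_end = numeric(), y_end = numeric(),
    t_start_ms = numeric(), t_end_ms = numeric()
  )
  if (nrow(fixations) == 0) return(empty)
  out <- fixations %>%
    dplyr::group_by(image_id, observer_id) %>%
    dplyr::arrange(t_start_ms, .by_group = TRUE) %>%
    dplyr::reframe(
      x_start = utils::head(x, -1), y_start = utils::head(y, -1),
      x_end = x[-1], y_end = y[-1],
      sacc_start = utils::head(t_end_ms, -1),
      sacc_end = t_start_ms[-1]
    ) %>%
    dplyr::rename(t_start_ms = sacc_start, t_end_ms = sacc_end)
  if (nrow(out) == 0) return(empty)
  as_tibble(out)
}
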