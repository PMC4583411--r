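#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-fold evaluation results
#'
#' @param x A `gaze_eval` object from [train_eval()].
#' @param ... Unused.
#' @return Tibble with one row per fold: repeat/fold indices, kernel, chosen
#'   hyperparameters, Bookmaker informedness and accuracy.
#' @method tidy gaze_eval
#' @export
tidy.gaze_eval <- function(x, ...) {
  dplyr::select(x$folds, -dplyr::any_of("confusion"))
}

#' One-row summary of an evaluation
#'
#' @param x A `gaze_eval` object from [train_eval()].
#' @param ... Unused.
#' @return Tibble with `kernel`, `n_folds`, `mean_bookmaker`, `se_bookmaker`,
#'   `mean_accuracy`, `se_accuracy`.
#' @method glance gaze_eval
#' @export
glance.gaze_eval <- function(x, ...) {
  s <- aggregate_folds(x)
  tibble::tibble(
    kernel = x$kernel, n_folds = s$n_folds,
    mean_bookmaker = s$mean_bookmaker, se_bookmaker = s$se_bookmaker,
    mean_accuracy = s$mean_accuracy, se_accuracy = s$se_accuracy
  )
}

#' Tidy a fusion report
#'
#' @param x A `fusion_report` from [run_fusion()].
#' @param ... Unused.
#' @return The method x kernel summary tibble.
#' @method tidy fusion_report
#' @export
tidy.fusion_report <- function(x, ...) x$summary

#' Tidy a selection mask
#'
#' @param x A [selection_mask()].
#' @param ... Unused.
#' @return Tibble with `element`, `selected`, plus `method` and
#'   `granularity`.
#' @method tidy selection_mask
#' @export
tidy.selection_mask <- function(x, ...) {
  tibble::tibble(
    element = seq_along(x$mask), selected = x$mask,
    method = x$method, granularity = x$granularity
  )
}
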