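#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_raster
#'   geom_point labs scale_fill_viridis_c coord_fixed theme_minimal
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot a saliency map
#'
#' Raster view of the full-resolution fixation-density map, with the image's
#' fixations optionally overlaid.
#'
#' @param object A [compute_saliency_map()] result.
#' @param fixations Optional fixation table to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, fixations = NULL, ...) {
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object$full_map)),
    x = seq_len(ncol(object$full_map))
  )
  df$saliency <- as.vector(t(object$full_map))
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$saliency)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    coord_fixed() +
    labs(x = "x (px)", y = "y (px)", fill = "saliency") +
    theme_minimal()
  if (!is.null(fixations)) {
    p <- p + geom_point(
      data = as.data.frame(fixations),
      aes(x = .data$x, y = .data$y), inherit.aes = FALSE,
      shape = 3, colour = "white", size = 1
    )
  }
  p
}

#' Plot a baseline report
#'
#' Bar chart of mean Bookmaker informedness per feature set and kernel, with
#' standard-error bars — the per-feature baseline comparison.
#'
#' @param object A `baseline_report` from [run_baseline()].
#' @param metric `"bookmaker"` (default) or `"accuracy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot baseline_report
#' @export
autoplot.baseline_report <- function(object, metric = c("bookmaker", "accuracy"),
                                     ...) {
  metric <- match.arg(metric)
  ycol <- paste0("mean_", metric)
  secol <- paste0("se_", metric)
  df <- as.data.frame(object)
  df$feature_set <- stats::reorder(df$feature_set, df[[ycol]])
  ggplot(df, aes(x = .data$feature_set, y = .data[[ycol]],
                 fill = .data$kernel)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(
      aes(ymin = .data[[ycol]] - .data[[secol]],
          ymax = .data[[ycol]] + .data[[secol]]),
      position = position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = paste("mean", metric)) +
    theme_minimal()
}

#' Plot a contribution report
#'
#' Bar chart of the mean fraction of each feature block's dimensions selected
#' across runs, ordered by rank.
#'
#' @param object A `contribution_report` from [contribution_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contribution_report
#' @export
autoplot.contribution_report <- function(object, ...) {
  df <- as.data.frame(object)
  df$block <- stats::reorder(df$block, df$mean_fraction)
  ggplot(df, aes(x = .data$block, y = .data$mean_fraction)) +
    geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "mean fraction of dimensions selected") +
    theme_minimal()
}

#' Plot a fusion report
#'
#' Bar chart of mean Bookmaker per reduction/selection method and kernel.
#'
#' @param object A `fusion_report` from [run_fusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_report
#' @export
autoplot.fusion_report <- function(object, ...) {
  df <- as.data.frame(object$summary)
  ggplot(df, aes(x = .data$method, y = .data$mean_bookmaker,
                 fill = .data$kernel)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(
      aes(ymin = .data$mean_bookmaker - .data$se_bookmaker,
          ymax = .data$mean_bookmaker + .data$se_bookmaker),
      position = position_dodge(width = 0.8), width = 0.25
    ) +
    labs(x = NULL, y = "mean Bookmaker informedness") +
    theme_minimal()
}
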