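#' Multiclass Bookmaker informedness
#'
#' Chance-corrected classification score. In the one-versus-rest
#' decomposition of a confusion matrix (rows = true class, columns =
#' predicted class), each class c has recall `TP / (TP + FN)` and inverse
#' recall `TN / (TN + FP)`; its informedness is Youden's J,
#' `recall + inverse recall - 1`. The multiclass score is the
#' prevalence-weighted average of the per-class informedness values (weights
#' proportional to row sums), following Powers' Bookmaker generalization.
#' It is +1 for a perfectly correct classifier, 0 exactly whenever the
#' prediction distribution is independent of the true class (rows mutually
#' proportional), and -1 for a perversely incorrect binary classifier.
#' A class with an empty row contributes informedness 0 at zero weight.
#'
#' @param confusion Square numeric matrix of non-negative counts, rows = true
#'   class, columns = predicted class.
#' @param weighted Prevalence-weighted average (default) or unweighted macro
#'   average over classes with at least one test item.
#' @return A single number in \[-1, 1\].
#' @examples
#' bookmaker(diag(c(4, 7, 4)))            # 1
#' bookmaker(outer(c(1, 2, 3), c(2, 1, 1))) # 0: rows proportional
#' @export
bookmaker <- function(confusion, weighted = TRUE) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    abort("`confusion` must be square (true classes x predicted classes).")
  }
  if (any(confusion < 0)) abort("confusion counts must be non-negative.")
  total <- sum(confusion)
  if (total == 0) abort("empty confusion matrix: informedness undefined.")
  row_sums <- rowSums(confusion)
  col_sums <- colSums(confusion)
  j <- vapply(seq_len(nrow(confusion)), function(c) {
    if (row_sums[c] == 0) return(0)
    tp <- confusion[c, c]
    fp <- col_sums[c] - tp
    pos <- row_sums[c]
    neg <- total - pos # TN + FP
    # recall + inverse recall - 1 == tp/pos - fp/neg; the subtraction form is
    # exact (0.0) when the prediction distribution is truth-independent
    if (neg > 0) tp / pos - fp / neg else tp / pos - 1
  }, numeric(1))
  if (weighted) {
    sum(j * row_sums) / total
  } else {
    mean(j[row_sums > 0])
  }
}

#' Classification accuracy of a confusion matrix
#'
#' @param confusion Square count matrix (rows = true, columns = predicted).
#' @return Fraction of correct predictions, `trace / total`.
#' @examples
#' accuracy(diag(3))
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) abort("empty confusion matrix: accuracy undefined.")
  sum(diag(confusion)) / total
}

#' Aggregate per-fold evaluation results
#'
#' Means and standard errors (sample SD over sqrt of the number of folds) of
#' the Bookmaker and accuracy scores across all repeat x fold results, plus
#' the pooled confusion matrix.
#'
#' @param results A `gaze_eval` object from [train_eval()], or a tibble with
#'   columns `bookmaker`, `accuracy` and a list-column `confusion`.
#' @return List of class `gaze_eval_summary` with elements `mean_bookmaker`,
#'   `se_bookmaker`, `mean_accuracy`, `se_accuracy`, `n_folds`,
#'   `pooled_confusion`.
#' @export
aggregate_folds <- function(results) {
  res <- if (inherits(results, "gaze_eval")) results$folds else results
  if (nrow(res) == 0) abort("no fold results to aggregate.")
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  pooled <- Reduce(`+`, res$confusion)
  structure(
    list(
      mean_bookmaker = mean(res$bookmaker),
      se_bookmaker = se(res$bookmaker),
      mean_accuracy = mean(res$accuracy),
      se_accuracy = se(res$accuracy),
      n_folds = nrow(res),
      pooled_confusion = pooled
    ),
    class = "gaze_eval_summary"
  )
}

#' @export
print.gaze_eval_summary <- function(x, ...) {
  cat(sprintf(
    "<gaze_eval_summary> %d folds | bookmaker %.3f (SE %.3f) | accuracy %.1f%% (SE %.1f)\n",
    x$n_folds, x$mean_bookmaker, x$se_bookmaker,
    100 * x$mean_accuracy, 100 * x$se_accuracy
  ))
  cat("pooled confusion (rows = true):\n")
  print(x$pooled_confusion)
  invisible(x)
}
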