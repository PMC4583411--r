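#' Build a repeated stratified cross-validation plan
#'
#' The evaluation protocol is repeated cross-validation: `repeats`
#' repetitions of a `folds`-fold scheme whose train / validation / test
#' proportions default to 0.9 / 0.05 / 0.05. Validation and test sets are
#' drawn with an equal number of items per class (a conservative stratified
#' draw): each holds `max(1, round(ratio * n_min))` items per class, where
#' `n_min` is the size of the smallest class, so that their per-class counts
#' are identical in every fold; the remaining items form the training set.
#' Folds are independent stratified draws, deterministic under `seed`.
#'
#' @param labels Factor (or character) of per-item class labels, or a
#'   `gaze_recordset` (whose image labels are used, in `image_id` order).
#' @param repeats,folds Repetitions and folds per repetition (default 10, 10).
#' @param ratios Train/validation/test proportions; must sum to 1.
#' @param seed Integer seed making the plan reproducible.
#' @return Object of class `cv_plan`: list with `assignments` (tibble of
#'   `repeat_idx`, `fold_idx`, `role`, `index`), `labels`, `repeats`,
#'   `folds`, `ratios`, `seed`.
#' @examples
#' plan <- make_cv_plan(factor(rep(c("a", "b", "c"), c(24, 47, 24))), seed = 1)
#' plan
#' @export
make_cv_plan <- function(labels, repeats = 10, folds = 10,
                         ratios = c(0.9, 0.05, 0.05), seed = 1) {
  if (inherits(labels, "gaze_recordset")) {
    labels <- labels$labels$valence_class[order(labels$labels$image_id)]
  }
  labels <- factor(labels)
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3 || any(ratios <= 0)) {
    abort("`ratios` must be three positive proportions summing to 1.")
  }
  counts <- table(labels)
  if (any(counts < folds)) {
    abort(sprintf(
      "class '%s' has fewer items (%d) than folds (%d).",
      names(counts)[which.min(counts)], min(counts), folds
    ))
  }
  n_min <- min(counts)
  per_class_val <- max(1L, round(ratios[2] * n_min))
  per_class_test <- max(1L, round(ratios[3] * n_min))
  if (per_class_val + per_class_test >= n_min) {
    abort("validation + test draw exhausts the smallest class.")
  }
  class_idx <- split(seq_along(labels), labels)
  assignments <- with_seed(seed, {
    purrr::map(seq_len(repeats), function(r) {
      purrr::map(seq_len(folds), function(f) {
        val <- integer(); tst <- integer()
        for (cl in class_idx) {
          drawn <- sample(cl, per_class_val + per_class_test)
          val <- c(val, drawn[seq_len(per_class_val)])
          tst <- c(tst, drawn[per_class_val + seq_len(per_class_test)])
        }
        trn <- setdiff(seq_along(labels), c(val, tst))
        tibble::tibble(
          repeat_idx = r, fold_idx = f,
          role = rep(c("train", "validation", "test"),
                     c(length(trn), length(val), length(tst))),
          index = c(sort(trn), sort(val), sort(tst))
        )
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
  })
  structure(
    list(assignments = assignments, labels = labels, repeats = repeats,
         folds = folds, ratios = ratios, seed = seed),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf(
    "<cv_plan> %d repeats x %d folds over %d items (%s), ratios %s, seed %d\n",
    x$repeats, x$folds, length(x$labels),
    paste(sprintf("%s=%d", levels(x$labels), table(x$labels)), collapse = ", "),
    paste(x$ratios, collapse = "/"), x$seed
  ))
  invisible(x)
}

# index sets of one fold
fold_indices <- function(plan, r, f) {
  a <- plan$assignments
  sel <- a[a$repeat_idx == r & a$fold_idx == f, ]
  list(
    train = sel$index[sel$role == "train"],
    validation = sel$index[sel$role == "validation"],
    test = sel$index[sel$role == "test"]
  )
}
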