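#' Default SVM hyperparameter grids
#'
#' Small per-kernel grids searched on each fold's validation set by Bookmaker
#' informedness. `gamma` is expressed as a multiple of the `1/d` heuristic
#' (`d` = number of feature dimensions).
#'
#' @param kernel One of `"linear"`, `"polynomial"`, `"radial"`.
#' @return Tibble of hyperparameter combinations (`cost`, and `gamma_mult` /
#'   `degree` where the kernel uses them).
#' @export
svm_grid <- function(kernel = c("linear", "polynomial", "radial")) {
  kernel <- match.arg(kernel)
  switch(kernel,
    linear = tidyr::expand_grid(cost = c(0.1, 1, 10)),
    polynomial = tidyr::expand_grid(cost = c(0.1, 1, 10), degree = c(2, 3)),
    radial = tidyr::expand_grid(cost = c(1, 10), gamma_mult = c(0.5, 1, 2))
  )
}

# fit one binary margin classifier per class (1-versus-rest)
fit_ovr_svm <- function(x, y, kernel, cost = 1, gamma_mult = 1, degree = 3) {
  classes <- levels(y)
  gamma <- gamma_mult / max(1L, ncol(x))
  models <- lapply(classes, function(cl) {
    y_bin <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(
      x = x, y = y_bin, kernel = kernel, cost = cost, gamma = gamma,
      degree = degree, coef0 = if (kernel == "polynomial") 1 else 0,
      scale = FALSE
    )
  })
  structure(list(models = models, classes = classes), class = "ovr_svm")
}

# n x k matrix of decision scores, oriented so larger = more that class
ovr_decision <- function(fit, newx) {
  scores <- vapply(fit$models, function(m) {
    dv <- attr(stats::predict(m, newx, decision.values = TRUE),
               "decision.values")
    v <- as.numeric(dv[, 1])
    # libsvm orients the value toward the first training label it saw;
    # flip when that was "rest"
    if (colnames(dv)[1] == "rest/pos") v <- -v
    v
  }, numeric(nrow(newx)))
  matrix(scores, nrow = nrow(newx),
         dimnames = list(NULL, fit$classes))
}

predict_ovr <- function(fit, newx) {
  sc <- ovr_decision(fit, newx)
  factor(fit$classes[max.col(sc, ties.method = "first")],
         levels = fit$classes)
}

# train-set standardization; constant dimensions pass through unscaled
standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, sdev, "/")
}

as_feature_matrix <- function(features) {
  if (is_tibble(features) || is.data.frame(features)) {
    df <- as.data.frame(features)
    if ("image_id" %in% names(df)) df$image_id <- NULL
    as.matrix(df)
  } else {
    as.matrix(features)
  }
}

#' Cross-validated one-versus-rest SVM evaluation
#'
#' For each repeat x fold of the plan: standardizes features on the training
#' set, picks the kernel's hyperparameters from [svm_grid()] by Bookmaker
#' informedness on the validation set, refits the three one-versus-rest
#' classifiers on the training set, and scores the test set. Folds whose
#' training set misses a class are skipped with a warning (impossible under
#' the default plan).
#'
#' @param features Feature table (tibble with optional `image_id` column,
#'   data frame or matrix), rows aligned with the plan's labels.
#' @param plan A [make_cv_plan()] over the same items.
#' @param kernel SVM kernel: `"linear"`, `"polynomial"` or `"radial"`.
#' @param grid Hyperparameter grid (default [svm_grid()] for the kernel).
#' @param labels Optional label factor overriding `plan$labels`.
#' @return Object of class `gaze_eval`: list with `folds` (tibble of
#'   `repeat_idx`, `fold_idx`, `kernel`, hyperparameters, list-column
#'   `confusion`, `bookmaker`, `accuracy`) and `kernel`. Summarize with
#'   [aggregate_folds()], [tidy()] or [glance()].
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60, 0), 12), matrix(rnorm(60, 3), 12),
#'            matrix(rnorm(60, -3), 12))
#' y <- factor(rep(c("unpleasant", "neutral", "pleasant"), each = 12))
#' plan <- make_cv_plan(y, repeats = 2, folds = 2, seed = 1)
#' glance(train_eval(X, plan, kernel = "linear"))
#' }
#' @export
train_eval <- function(features, plan, kernel = c("linear", "polynomial", "radial"),
                       grid = svm_grid(kernel), labels = NULL) {
  kernel <- match.arg(kernel)
  X <- as_feature_matrix(features)
  y <- labels %||% plan$labels
  y <- factor(y)
  if (nrow(X) != length(y)) {
    abort("feature rows and labels are not aligned.")
  }
  folds <- tidyr::expand_grid(repeat_idx = seq_len(plan$repeats),
                              fold_idx = seq_len(plan$folds))
  rows <- purrr::pmap(folds, function(repeat_idx, fold_idx) {
    idx <- fold_indices(plan, repeat_idx, fold_idx)
    y_train <- droplevels(y[idx$train])
    if (nlevels(y_train) < nlevels(y)) {
      warn(sprintf("skipping repeat %d fold %d: class missing from training set.",
                   repeat_idx, fold_idx))
      return(NULL)
    }
    std <- standardizer(X[idx$train, , drop = FALSE])
    x_train <- std(X[idx$train, , drop = FALSE])
    x_val <- std(X[idx$validation, , drop = FALSE])
    x_test <- std(X[idx$test, , drop = FALSE])

    scores <- purrr::pmap_dbl(grid, function(...) {
      pars <- list(...)
      fit <- fit_ovr_svm(x_train, y[idx$train], kernel,
                         cost = pars$cost %||% 1,
                         gamma_mult = pars$gamma_mult %||% 1,
                         degree = pars$degree %||% 3)
      pred <- predict_ovr(fit, x_val)
      bookmaker(confusion_counts(y[idx$validation], pred))
    })
    best <- grid[which.max(scores), ]
    fit <- fit_ovr_svm(x_train, y[idx$train], kernel,
                       cost = grid_par(best, "cost", 1),
                       gamma_mult = grid_par(best, "gamma_mult", 1),
                       degree = grid_par(best, "degree", 3))
    pred <- predict_ovr(fit, x_test)
    cm <- confusion_counts(y[idx$test], pred)
    dplyr::bind_cols(
      tibble::tibble(repeat_idx = repeat_idx, fold_idx = fold_idx,
                     kernel = kernel),
      best,
      tibble::tibble(confusion = list(cm),
                     bookmaker = bookmaker(cm), accuracy = accuracy(cm))
    )
  })
  folds_tbl <- dplyr::bind_rows(purrr::compact(rows))
  structure(list(folds = folds_tbl, kernel = kernel, levels = levels(y)),
            class = "gaze_eval")
}

#' Confusion matrix of counts
#'
#' @param truth,predicted Factors over the same levels.
#' @return Square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  unclass(table(truth = truth, predicted = predicted))
}

#' @export
print.gaze_eval <- function(x, ...) {
  cat(sprintf("<gaze_eval> kernel = %s, %d folds\n", x$kernel, nrow(x$folds)))
  print(aggregate_folds(x))
  invisible(x)
}

grid_par <- function(tbl, nm, default) {
  if (nm %in% names(tbl)) tbl[[nm]] else default
}
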