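#' Baseline evaluation of each feature representation
#'
#' Runs the cross-validated SVM over (a) each of the ten histogram/map
#' feature blocks individually, (b) their 872-dimensional concatenation
#' (`full_set`) and (c) each of the six normalized mean-value features, for
#' every requested kernel, and reports the mean Bookmaker informedness and
#' accuracy with standard errors — the per-feature baseline comparison.
#'
#' @param recordset A [gaze_recordset()], or `NULL` if `features`,
#'   `means` and `labels` are supplied directly.
#' @param kernels Character vector of kernels to run.
#' @param repeats,folds,ratios Cross-validation plan parameters.
#' @param seed Seed for the plan.
#' @param features Optional precomputed [extract_features()] table.
#' @param means Optional precomputed [mean_features()] table.
#' @param labels Optional label factor aligned with the feature rows.
#' @param feature_sets Restrict to a subset of feature-set names.
#' @return Tibble of class `baseline_report`: one row per feature set x
#'   kernel with `feature_set`, `kind` (block / full / mean), `kernel`,
#'   `n_dims`, `mean_bookmaker`, `se_bookmaker`, `mean_accuracy`,
#'   `se_accuracy`. Fold-level results are attached as attribute `"folds"`.
#' @export
run_baseline <- function(recordset = NULL,
                         kernels = c("linear", "polynomial", "radial"),
                         repeats = 10, folds = 10,
                         ratios = c(0.9, 0.05, 0.05), seed = 1,
                         features = NULL, means = NULL, labels = NULL,
                         feature_sets = NULL) {
  if (!is.null(recordset)) {
    features <- features %||% extract_features(recordset)
    means <- means %||% mean_features(recordset)
    labs <- recordset$labels
    labels <- labels %||%
      labs$valence_class[match(features$image_id, labs$image_id)]
  }
  if (is.null(features) || is.null(labels)) {
    abort("supply a recordset, or `features` (+ `means`) and `labels`.")
  }
  blocks <- feature_blocks()
  X <- as_feature_matrix(features)
  sets <- c(
    stats::setNames(
      purrr::map(seq_len(nrow(blocks)),
                 function(b) X[, blocks$start[b]:blocks$end[b], drop = FALSE]),
      blocks$block
    ),
    list(full_set = X)
  )
  kinds <- c(rep("block", nrow(blocks)), "full")
  if (!is.null(means)) {
    mcols <- setdiff(names(means), "image_id")
    sets <- c(sets, stats::setNames(
      purrr::map(mcols, function(cn) matrix(means[[cn]], ncol = 1)),
      mcols
    ))
    kinds <- c(kinds, rep("mean", length(mcols)))
  }
  if (!is.null(feature_sets)) {
    keep <- names(sets) %in% feature_sets
    sets <- sets[keep]; kinds <- kinds[keep]
  }
  plan <- make_cv_plan(labels, repeats = repeats, folds = folds,
                       ratios = ratios, seed = seed)
  all_folds <- list()
  rows <- purrr::imap(sets, function(Xs, nm) {
    purrr::map(kernels, function(k) {
      ev <- train_eval(Xs, plan, kernel = k)
      all_folds[[paste(nm, k, sep = ".")]] <<- ev$folds
      s <- aggregate_folds(ev)
      tibble::tibble(
        feature_set = nm, kind = kinds[[which(names(sets) == nm)]],
        kernel = k, n_dims = ncol(Xs),
        mean_bookmaker = s$mean_bookmaker, se_bookmaker = s$se_bookmaker,
        mean_accuracy = s$mean_accuracy, se_accuracy = s$se_accuracy
      )
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  attr(rows, "folds") <- all_folds
  class(rows) <- c("baseline_report", class(rows))
  rows
}

#' Feature fusion: reduction/selection methods compared
#'
#' Runs each configured reduction or wrapper-selection method for each
#' kernel over the cross-validation plan and reports mean Bookmaker and
#' accuracy, together with the selection masks produced by the wrapper
#' methods and, when dimension-granularity masks are available, the
#' feature-contribution report.
#'
#' Decomposition methods (`pca`, `svd`) are refit inside every fold on that
#' fold's training rows. Wrapper methods (`sfs`, `sbs`, `ga`, `pso`) search
#' once per repeat on the repeat's first fold (at `granularity`), then the
#' selected mask is evaluated over the repeat's folds; `full_set` is the
#' no-reduction reference.
#'
#' @param features [extract_features()] table (or matrix) of the dataset.
#' @param labels Label factor aligned with the feature rows.
#' @param methods Subset of `c("full_set", "pca", "svd", "sfs", "sbs", "ga",
#'   "pso")`.
#' @param kernels Kernels to run.
#' @param granularity Wrapper mask granularity: `"block"` (fast, default) or
#'   `"dimension"`.
#' @param repeats,folds,ratios,seed Cross-validation plan parameters.
#' @param variance_threshold Explained-variance threshold for `pca`/`svd`.
#' @param ga_params,pso_params Named lists overriding the optimizer defaults
#'   (`pop_size`, `generations`, ... / `swarm_size`, `iterations`, ...).
#' @return List of class `fusion_report` with `summary` (tibble: method x
#'   kernel with means and SEs), `masks` (list of [selection_mask()]),
#'   `contribution` ([contribution_analysis()] tibble or `NULL`).
#' @export
run_fusion <- function(features, labels,
                       methods = c("full_set", "pca", "svd", "sfs", "sbs",
                                   "ga", "pso"),
                       kernels = "linear",
                       granularity = c("block", "dimension"),
                       repeats = 10, folds = 10, ratios = c(0.9, 0.05, 0.05),
                       seed = 1, variance_threshold = 0.9,
                       ga_params = list(), pso_params = list()) {
  granularity <- match.arg(granularity)
  methods <- match.arg(methods, several.ok = TRUE)
  X <- as_feature_matrix(features)
  labels <- factor(labels)
  plan <- make_cv_plan(labels, repeats = repeats, folds = folds,
                       ratios = ratios, seed = seed)
  blocks <- feature_blocks()
  use_blocks <- granularity == "block" && ncol(X) == sum(blocks$size)
  n_elem <- if (use_blocks) nrow(blocks) else ncol(X)
  seeds <- child_seeds(seed, plan$repeats * 2L)

  masks <- list()
  summary_rows <- list()
  for (m in methods) {
    for (k in kernels) {
      fold_scores <- list()
      for (r in seq_len(plan$repeats)) {
        mask_dims <- NULL
        if (m %in% c("sfs", "sbs", "ga", "pso")) {
          fitness <- wrapper_objective(
            X, plan, kernel = k,
            granularity = if (use_blocks) "block" else "dimension",
            blocks = blocks, repeat_idx = r, fold_idx = 1
          )
          msk <- switch(m,
            sfs = sequential_select(fitness, n_elem, "forward",
                                    granularity = if (use_blocks) "block" else "dimension"),
            sbs = sequential_select(fitness, n_elem, "backward",
                                    granularity = if (use_blocks) "block" else "dimension"),
            ga = do.call(ga_select, c(
              list(fitness = fitness, n_elements = n_elem,
                   seed = seeds[2 * r - 1],
                   granularity = if (use_blocks) "block" else "dimension"),
              ga_params
            )),
            pso = do.call(pso_select, c(
              list(fitness = fitness, n_elements = n_elem,
                   seed = seeds[2 * r],
                   granularity = if (use_blocks) "block" else "dimension"),
              pso_params
            ))
          )
          msk$provenance$repeat_idx <- r
          msk$provenance$kernel <- k
          masks[[paste(m, k, r, sep = ".")]] <- msk
          mask_dims <- if (msk$granularity == "block") {
            expand_block_mask(msk$mask, blocks)
          } else msk$mask
        }
        for (f in seq_len(plan$folds)) {
          idx <- fold_indices(plan, r, f)
          if (m %in% c("pca", "svd")) {
            red <- variance_reduce(X[idx$train, , drop = FALSE],
                                   threshold = variance_threshold, method = m)
            Xf <- red$transform(X)
          } else if (!is.null(mask_dims)) {
            Xf <- X[, mask_dims, drop = FALSE]
          } else {
            Xf <- X
          }
          std <- standardizer(Xf[idx$train, , drop = FALSE])
          grid <- svm_grid(k)
          scores <- purrr::pmap_dbl(grid, function(...) {
            pars <- list(...)
            fit <- fit_ovr_svm(std(Xf[idx$train, , drop = FALSE]),
                               labels[idx$train], k,
                               cost = pars$cost %||% 1,
                               gamma_mult = pars$gamma_mult %||% 1,
                               degree = pars$degree %||% 3)
            bookmaker(confusion_counts(
              labels[idx$validation],
              predict_ovr(fit, std(Xf[idx$validation, , drop = FALSE]))
            ))
          })
          best <- grid[which.max(scores), ]
          fit <- fit_ovr_svm(std(Xf[idx$train, , drop = FALSE]),
                             labels[idx$train], k,
                             cost = grid_par(best, "cost", 1),
                             gamma_mult = grid_par(best, "gamma_mult", 1),
                             degree = grid_par(best, "degree", 3))
          cm <- confusion_counts(
            labels[idx$test],
            predict_ovr(fit, std(Xf[idx$test, , drop = FALSE]))
          )
          fold_scores[[length(fold_scores) + 1L]] <- tibble::tibble(
            repeat_idx = r, fold_idx = f,
            confusion = list(cm),
            bookmaker = bookmaker(cm), accuracy = accuracy(cm)
          )
        }
      }
      fs <- dplyr::bind_rows(fold_scores)
      s <- aggregate_folds(fs)
      summary_rows[[paste(m, k, sep = ".")]] <- tibble::tibble(
        method = m, kernel = k,
        mean_bookmaker = s$mean_bookmaker, se_bookmaker = s$se_bookmaker,
        mean_accuracy = s$mean_accuracy, se_accuracy = s$se_accuracy
      )
    }
  }
  dim_masks <- purrr::keep(masks, function(m) {
    m$granularity == "dimension" || length(m$mask) == nrow(blocks)
  })
  contribution <- if (length(dim_masks) && ncol(X) == sum(blocks$size)) {
    contribution_analysis(dim_masks, blocks)
  } else NULL
  structure(
    list(summary = dplyr::bind_rows(summary_rows), masks = masks,
         contribution = contribution, plan = plan),
    class = "fusion_report"
  )
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf("<fusion_report> %d method x kernel cells, %d masks\n",
              nrow(x$summary), length(x$masks)))
  print(x$summary)
  invisible(x)
}

#' Export a fusion report
#'
#' Writes the method x kernel summary and the masks as CSV and the summary as
#' JSON, mirroring the package's stable report schemas.
#'
#' @param report A [run_fusion()] result.
#' @param dir Output directory (created if needed).
#' @return `report`, invisibly.
#' @export
write_fusion_report <- function(report, dir) {
  stopifnot(inherits(report, "fusion_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$summary, file.path(dir, "fusion_summary.csv"))
  jsonlite::write_json(report$summary, file.path(dir, "fusion_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(report$masks)) {
    mask_tbl <- purrr::imap(report$masks, function(m, nm) {
      tibble::tibble(run = nm, method = m$method, granularity = m$granularity,
                     element = seq_along(m$mask), selected = m$mask)
    }) %>% dplyr::bind_rows()
    readr::write_csv(mask_tbl, file.path(dir, "selection_masks.csv"))
  }
  if (!is.null(report$contribution)) {
    readr::write_csv(report$contribution, file.path(dir, "contribution.csv"))
  }
  invisible(report)
}

#' The curated affective picture set
#'
#' The 95 IAPS picture identifiers (people and daily-activity scenes) that
#' form the reference study set, with their valence class: 47 neutral, 24
#' pleasant and 24 unpleasant. Shipped as a plain CSV in `extdata`; useful
#' for bookkeeping checks and for joining externally obtained gaze data onto
#' the study set.
#'
#' @return Tibble with columns `image_id` (character) and `valence_class`
#'   (factor).
#' @examples
#' dplyr::count(curated_image_set(), valence_class)
#' @export
curated_image_set <- function() {
  path <- system.file("extdata", "curated_iaps_set.csv",
                      package = "gazevalence", mustWork = TRUE)
  out <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    valence_class = readr::col_character()
  ))
  out$valence_class <- factor(out$valence_class, levels = valence_levels)
  out
}
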