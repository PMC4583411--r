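#' Selection masks
#'
#' Wrapper selection methods return a binary mask over either the individual
#' feature dimensions (`"dimension"` granularity) or the ten feature blocks
#' (`"block"` granularity), together with the objective value the mask
#' achieved and its provenance.
#'
#' @param mask Logical vector; at least one element selected.
#' @param granularity `"dimension"` or `"block"`.
#' @param method Token identifying the producing method.
#' @param objective_value Objective (validation Bookmaker) achieved.
#' @param provenance Optional list (e.g. repeat/fold indices).
#' @return Object of class `selection_mask`.
#' @export
selection_mask <- function(mask, granularity = c("dimension", "block"),
                           method = "manual", objective_value = NA_real_,
                           provenance = list()) {
  granularity <- match.arg(granularity)
  mask <- as.logical(mask)
  if (!any(mask)) abort("a selection mask must select at least one element.")
  structure(
    list(mask = mask, granularity = granularity, method = method,
         objective_value = objective_value, provenance = provenance),
    class = "selection_mask"
  )
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %s (%s): %d / %d selected, objective %.4f\n",
              x$method, x$granularity, sum(x$mask), length(x$mask),
              x$objective_value))
  invisible(x)
}

# expand a block-granularity mask to dimension granularity
expand_block_mask <- function(mask, blocks = feature_blocks()) {
  stopifnot(length(mask) == nrow(blocks))
  rep(mask, blocks$size)
}

#' Wrapper objective: validation Bookmaker of a masked SVM
#'
#' Builds the fitness function the wrapper selection methods (SFS/SBS, GA,
#' PSO) maximize: restrict the features to the mask, standardize on one fixed
#' fold's training set, fit the one-versus-rest SVM and score the fold's
#' validation set by Bookmaker informedness. Reusing a single fold per
#' candidate bounds the cost of the search; the returned mask is then
#' typically re-evaluated on the full plan.
#'
#' @param features Feature table or matrix, rows aligned with `plan$labels`.
#' @param plan A [make_cv_plan()].
#' @param kernel SVM kernel (default linear).
#' @param granularity Mask granularity; `"block"` masks are expanded through
#'   `blocks` before indexing columns.
#' @param blocks Block schema used for `"block"` granularity (default
#'   [feature_blocks()]; must match `ncol(features)`).
#' @param repeat_idx,fold_idx The fold whose validation set scores candidates.
#' @param cost SVM regularization constant (fixed during the search).
#' @return `function(mask) -> numeric`; an all-zero mask scores -1.
#' @export
wrapper_objective <- function(features, plan, kernel = "linear",
                              granularity = c("dimension", "block"),
                              blocks = feature_blocks(),
                              repeat_idx = 1, fold_idx = 1, cost = 1) {
  granularity <- match.arg(granularity)
  X <- as_feature_matrix(features)
  y <- plan$labels
  idx <- fold_indices(plan, repeat_idx, fold_idx)
  function(mask) {
    mask <- as.logical(mask)
    dims <- if (granularity == "block") expand_block_mask(mask, blocks) else mask
    if (!any(dims)) return(-1)
    Xs <- X[, dims, drop = FALSE]
    std <- standardizer(Xs[idx$train, , drop = FALSE])
    fit <- fit_ovr_svm(std(Xs[idx$train, , drop = FALSE]), y[idx$train],
                       kernel = kernel, cost = cost)
    pred <- predict_ovr(fit, std(Xs[idx$validation, , drop = FALSE]))
    bookmaker(confusion_counts(y[idx$validation], pred))
  }
}

#' Sequential forward / backward feature selection
#'
#' Greedy wrapper search: forward selection starts from the empty mask and at
#' each step adds the single element whose addition maximizes the objective;
#' backward selection starts from the full mask and removes the element whose
#' removal maximizes it. The search stops when no single change strictly
#' improves the objective. Ties break toward the lowest index, making the
#' trajectory deterministic.
#'
#' @param fitness Objective `function(mask) -> numeric` (see
#'   [wrapper_objective()]).
#' @param n_elements Mask length (number of dimensions or blocks).
#' @param direction `"forward"` or `"backward"`.
#' @param granularity Recorded in the returned mask.
#' @param method Token recorded in the returned mask.
#' @return A [selection_mask()].
#' @examples
#' # toy additive objective: elements 1 and 3 help, the rest hurt
#' fit <- function(m) sum(c(2, -1, 1, -1)[as.logical(m)])
#' sequential_select(fit, 4, "forward")$mask
#' @export
sequential_select <- function(fitness, n_elements,
                              direction = c("forward", "backward"),
                              granularity = "dimension",
                              method = NULL) {
  direction <- match.arg(direction)
  method <- method %||% if (direction == "forward") "sfs" else "sbs"
  mask <- rep(direction == "backward", n_elements)
  current <- if (direction == "backward") fitness(mask) else -Inf
  repeat {
    candidates <- if (direction == "forward") which(!mask) else which(mask)
    if (direction == "backward" && sum(mask) <= 1) break
    if (length(candidates) == 0) break
    vals <- vapply(candidates, function(i) {
      m <- mask
      m[i] <- !m[i]
      fitness(m)
    }, numeric(1))
    best <- which.max(vals)   # which.max takes the first (lowest index) tie
    if (vals[best] > current) {
      mask[candidates[best]] <- !mask[candidates[best]]
      current <- vals[best]
    } else break
  }
  selection_mask(mask, granularity = granularity, method = method,
                 objective_value = current)
}

#' Binary genetic algorithm feature selection
#'
#' Standard elitist binary GA maximizing the wrapper objective: tournament
#' selection (size 2), uniform crossover, independent bit mutation. The best
#' individual is carried over unchanged each generation, so the best-fitness
#' trajectory is monotone non-decreasing. All-zero offspring are repaired by
#' activating one random bit. Deterministic under `seed`.
#'
#' @param fitness Objective `function(mask) -> numeric`.
#' @param n_elements Mask length.
#' @param pop_size Population size (default 30).
#' @param generations Number of generations (default 100).
#' @param p_crossover Crossover probability (default 0.8).
#' @param p_mutation Per-bit mutation probability (default 0.02).
#' @param seed Integer seed.
#' @param granularity Recorded in the returned mask.
#' @param init Optional logical matrix of initial individuals (rows recycled
#'   to `pop_size`); random initialization when `NULL`.
#' @return A [selection_mask()] with the best-fitness trajectory in
#'   `provenance$trajectory`.
#' @export
ga_select <- function(fitness, n_elements, pop_size = 30, generations = 100,
                      p_crossover = 0.8, p_mutation = 0.02, seed = 1,
                      granularity = "dimension", init = NULL) {
  with_seed(seed, {
    pop <- init_population(init, pop_size, n_elements)
    pop <- t(apply(pop, 1, repair_mask))
    if (n_elements == 1) pop <- matrix(TRUE, pop_size, 1)
    fit <- apply(pop, 1, fitness)
    trajectory <- numeric(generations)
    for (g in seq_len(generations)) {
      elite_i <- which.max(fit)
      newpop <- matrix(FALSE, pop_size, n_elements)
      newpop[1, ] <- pop[elite_i, ]
      for (k in seq(2, pop_size)) {
        p1 <- tournament(fit)
        p2 <- tournament(fit)
        child <- if (stats::runif(1) < p_crossover) {
          pick <- stats::runif(n_elements) < 0.5
          ifelse(pick, pop[p1, ], pop[p2, ])
        } else pop[p1, ]
        flip <- stats::runif(n_elements) < p_mutation
        child[flip] <- !child[flip]
        newpop[k, ] <- repair_mask(child)
      }
      pop <- newpop
      fit <- c(fit[elite_i], apply(pop[-1, , drop = FALSE], 1, fitness))
      trajectory[g] <- max(fit)
    }
    best <- which.max(fit)
    selection_mask(pop[best, ], granularity = granularity, method = "ga",
                   objective_value = fit[best],
                   provenance = list(seed = seed, trajectory = trajectory))
  })
}

tournament <- function(fit, size = 2) {
  cand <- sample.int(length(fit), size)
  cand[which.max(fit[cand])]
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  mask
}

init_population <- function(init, n_rows, n_elements) {
  if (is.null(init)) {
    return(matrix(stats::runif(n_rows * n_elements) < 0.5, nrow = n_rows))
  }
  init <- matrix(as.logical(init), ncol = n_elements)
  init[rep_len(seq_len(nrow(init)), n_rows), , drop = FALSE]
}

#' Mutated binary particle swarm optimization feature selection
#'
#' Binary PSO with a sigmoid velocity transfer: real-valued velocities evolve
#' under inertia and cognitive/social attraction toward the personal and
#' global best masks, positions are re-sampled through the sigmoid of the
#' velocity, and a stochastic bit-flip mutation is applied to each particle.
#' The global best is never mutated in place, so its fitness trajectory is
#' monotone non-decreasing. Deterministic under `seed`.
#'
#' @param fitness Objective `function(mask) -> numeric`.
#' @param n_elements Mask length.
#' @param swarm_size Number of particles (default 30).
#' @param iterations PSO iterations (default 100).
#' @param inertia Velocity inertia weight (default 0.72).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 1.49).
#' @param p_mutation Per-bit mutation probability (default 0.05).
#' @param v_max Velocity clamp (default 4).
#' @param seed Integer seed.
#' @param granularity Recorded in the returned mask.
#' @param init Optional logical matrix of initial particle positions (rows
#'   recycled to `swarm_size`); random when `NULL`.
#' @param init_velocity Initial velocity range half-width (default 1; 0 gives
#'   zero starting velocities).
#' @return A [selection_mask()] with the global-best trajectory in
#'   `provenance$trajectory`.
#' @export
pso_select <- function(fitness, n_elements, swarm_size = 30, iterations = 100,
                       inertia = 0.72, c1 = 1.49, c2 = 1.49,
                       p_mutation = 0.05, v_max = 4, seed = 1,
                       granularity = "dimension", init = NULL,
                       init_velocity = 1) {
  with_seed(seed, {
    pos <- init_population(init, swarm_size, n_elements)
    pos <- t(apply(pos, 1, repair_mask))
    if (n_elements == 1) pos <- matrix(TRUE, swarm_size, 1)
    vel <- matrix(stats::runif(swarm_size * n_elements,
                               -init_velocity, init_velocity),
                  nrow = swarm_size)
    fit <- apply(pos, 1, fitness)
    pbest <- pos; pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    trajectory <- numeric(iterations)
    for (it in seq_len(iterations)) {
      r1 <- matrix(stats::runif(swarm_size * n_elements), swarm_size)
      r2 <- matrix(stats::runif(swarm_size * n_elements), swarm_size)
      vel <- inertia * vel +
        c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, swarm_size, n_elements, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, -v_max), v_max)
      prob <- 1 / (1 + exp(-vel))
      pos <- matrix(stats::runif(swarm_size * n_elements), swarm_size) < prob
      flip <- matrix(stats::runif(swarm_size * n_elements), swarm_size) < p_mutation
      pos[flip] <- !pos[flip]
      pos <- t(apply(pos, 1, repair_mask))
      if (n_elements == 1) pos <- matrix(TRUE, swarm_size, 1)
      fit <- apply(pos, 1, fitness)
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      if (max(pbest_fit) > gbest_fit) {
        g <- which.max(pbest_fit)
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
      trajectory[it] <- gbest_fit
    }
    selection_mask(gbest, granularity = granularity, method = "pso",
                   objective_value = gbest_fit,
                   provenance = list(seed = seed, trajectory = trajectory))
  })
}

#' Feature-contribution analysis over selection runs
#'
#' Summarizes a collection of dimension-granularity masks (one per selection
#' run, e.g. per repeat x fold): for each feature block, the mean fraction of
#' its dimensions selected across runs, with blocks ranked by that fraction.
#' Block-granularity masks are expanded to dimensions first, in which case
#' the fraction is the block's selection frequency.
#'
#' @param masks List of [selection_mask()] objects (or plain logical vectors
#'   at dimension granularity).
#' @param blocks Block schema (default [feature_blocks()]).
#' @return Tibble of class `contribution_report` with columns `block`,
#'   `size`, `mean_fraction`, `rank` (1 = most contributing), ordered by
#'   rank.
#' @export
contribution_analysis <- function(masks, blocks = feature_blocks()) {
  if (inherits(masks, "selection_mask")) masks <- list(masks)
  if (length(masks) == 0) abort("no masks supplied.")
  n_dims <- sum(blocks$size)
  dim_masks <- purrr::map(masks, function(m) {
    v <- if (inherits(m, "selection_mask")) {
      if (m$granularity == "block") expand_block_mask(m$mask, blocks) else m$mask
    } else as.logical(m)
    if (length(v) != n_dims) {
      abort(sprintf("mask length %d does not match the %d-dimensional schema.",
                    length(v), n_dims))
    }
    v
  })
  fractions <- vapply(seq_len(nrow(blocks)), function(b) {
    cols <- blocks$start[b]:blocks$end[b]
    mean(vapply(dim_masks, function(v) mean(v[cols]), numeric(1)))
  }, numeric(1))
  out <- tibble::tibble(
    block = blocks$block, size = blocks$size, mean_fraction = fractions
  )
  out$rank <- rank(-out$mean_fraction, ties.method = "min")
  out <- dplyr::arrange(out, rank, block)
  class(out) <- c("contribution_report", class(out))
  out
}
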