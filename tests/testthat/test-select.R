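# additive toy objective over mask bits, with per-element weights
additive_fitness <- function(w) function(mask) sum(w[as.logical(mask)])

# exhaustive optimum of an additive-with-interactions objective on few bits
exhaustive_best <- function(fitness, n) {
  best_val <- -Inf; best_mask <- NULL
  for (code in 1:(2^n - 1)) {
    m <- as.logical(bitwAnd(code, 2^(0:(n - 1))) > 0)
    v <- fitness(m)
    if (v > best_val) { best_val <- v; best_mask <- m }
  }
  list(mask = best_mask, value = best_val)
}

test_that("forward selection picks informative dimensions first", {
  w <- c(2, -1, 1.5, -0.5, 1, -2)
  msk <- sequential_select(additive_fitness(w), 6, "forward")
  expect_equal(msk$mask, w > 0)
  expect_equal(msk$objective_value, sum(w[w > 0]))
  expect_equal(msk$method, "sfs")
})

test_that("backward selection keeps the full mask when it is optimal", {
  w <- rep(1, 5)
  msk <- sequential_select(additive_fitness(w), 5, "backward")
  expect_true(all(msk$mask))
  expect_equal(msk$method, "sbs")
})

test_that("greedy trajectory matches brute-force greedy on few dimensions", {
  set.seed(31)
  for (rep in 1:5) {
    w <- rnorm(4)
    # interaction term makes the objective non-additive
    fitness <- function(m) {
      m <- as.logical(m)
      sum(w[m]) + 0.5 * (m[1] && m[3]) - 0.4 * (m[2] && m[4])
    }
    for (direction in c("forward", "backward")) {
      got <- sequential_select(fitness, 4, direction)
      # independent re-implementation of the greedy rule
      mask <- rep(direction == "backward", 4)
      cur <- if (direction == "backward") fitness(mask) else -Inf
      repeat {
        cand <- if (direction == "forward") which(!mask) else which(mask)
        if (length(cand) == 0 || (direction == "backward" && sum(mask) <= 1)) break
        vals <- sapply(cand, function(i) { m <- mask; m[i] <- !m[i]; fitness(m) })
        if (max(vals) > cur) {
          pick <- cand[which.max(vals)]
          mask[pick] <- !mask[pick]
          cur <- max(vals)
        } else break
      }
      expect_equal(got$mask, mask)
      expect_equal(got$objective_value, cur)
    }
  }
})

test_that("genetic algorithm solves degenerate and enumerable problems", {
  # degenerate objective: count of selected bits -> all-ones mask
  msk <- ga_select(function(m) sum(m), 8, pop_size = 12, generations = 30,
                   seed = 1)
  expect_true(all(msk$mask))
  # determinism under seed
  f <- additive_fitness(c(1, -2, 3, -1, 2, -3))
  m1 <- ga_select(f, 6, pop_size = 10, generations = 20, seed = 7)
  m2 <- ga_select(f, 6, pop_size = 10, generations = 20, seed = 7)
  expect_identical(m1$mask, m2$mask)
  # elitism makes the best-fitness trajectory non-decreasing
  expect_true(all(diff(m1$provenance$trajectory) >= 0))
})

test_that("GA recovers the exhaustive optimum on 6-bit toys", {
  set.seed(17)
  w <- rnorm(6)
  fitness <- function(m) {
    m <- as.logical(m)
    sum(w[m]) + 0.8 * (m[1] && m[2]) - 0.6 * (m[3] && m[4])
  }
  target <- exhaustive_best(fitness, 6)
  hits <- sum(vapply(1:20, function(s) {
    got <- ga_select(fitness, 6, pop_size = 20, generations = 50, seed = s)
    isTRUE(all.equal(got$objective_value, target$value))
  }, logical(1)))
  expect_gte(hits, 19)
})

test_that("binary PSO recovers optima and honors its fixed point", {
  set.seed(23)
  w <- rnorm(6)
  fitness <- additive_fitness(w)
  target <- exhaustive_best(fitness, 6)
  hits <- sum(vapply(1:20, function(s) {
    got <- pso_select(fitness, 6, swarm_size = 20, iterations = 50, seed = s)
    isTRUE(all.equal(got$objective_value, target$value))
  }, logical(1)))
  expect_gte(hits, 19)

  # no mutation, zero velocities, swarm initialized at the optimum:
  # the optimum is returned unchanged
  fixed <- pso_select(fitness, 6, swarm_size = 10, iterations = 20,
                      p_mutation = 0, init_velocity = 0,
                      init = matrix(target$mask, 1), seed = 3)
  expect_equal(fixed$mask, target$mask)
  expect_equal(fixed$objective_value, target$value)

  # determinism and monotone global-best trajectory
  p1 <- pso_select(fitness, 6, swarm_size = 10, iterations = 20, seed = 11)
  p2 <- pso_select(fitness, 6, swarm_size = 10, iterations = 20, seed = 11)
  expect_identical(p1$mask, p2$mask)
  expect_true(all(diff(p1$provenance$trajectory) >= 0))
})

test_that("contribution analysis averages per-block selection fractions", {
  blocks <- feature_blocks()
  n <- sum(blocks$size)
  # one mask selecting exactly the saliency_map block
  m1 <- rep(FALSE, n)
  m1[blocks$start[1]:blocks$end[1]] <- TRUE
  rep1 <- contribution_analysis(list(m1))
  expect_equal(rep1$mean_fraction[rep1$block == "saliency_map"], 1)
  expect_equal(sum(rep1$mean_fraction), 1)
  expect_equal(rep1$rank[rep1$block == "saliency_map"], 1)

  # half-selected in one run, empty in another -> fraction 0.25
  m2 <- rep(FALSE, n)
  m2[blocks$start[1]:(blocks$start[1] + blocks$size[1] / 2 - 1)] <- TRUE
  m3 <- rep(FALSE, n); m3[blocks$start[2]] <- TRUE
  rep2 <- contribution_analysis(list(m2, m3))
  expect_equal(rep2$mean_fraction[rep2$block == "saliency_map"], 0.25)

  # brute-force equivalence and run-order invariance on random masks
  set.seed(13)
  masks <- replicate(6, runif(n) < 0.3, simplify = FALSE)
  got <- contribution_analysis(masks)
  for (b in seq_len(nrow(blocks))) {
    cols <- blocks$start[b]:blocks$end[b]
    manual <- mean(sapply(masks, function(m) sum(m[cols]) / length(cols)))
    expect_equal(got$mean_fraction[got$block == blocks$block[b]], manual)
  }
  expect_equal(contribution_analysis(rev(masks))$mean_fraction,
               got$mean_fraction)
  expect_true(all(got$mean_fraction >= 0 & got$mean_fraction <= 1))
})

test_that("block masks expand through the schema", {
  blocks <- feature_blocks()
  bm <- selection_mask(c(TRUE, rep(FALSE, 9)), granularity = "block",
                       method = "ga")
  rep <- contribution_analysis(list(bm))
  expect_equal(rep$mean_fraction[rep$block == "saliency_map"], 1)
  expect_equal(sum(rep$mean_fraction > 0), 1)
})
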