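# Real-coded genetic algorithm over the (concentration, exposure) rectangle:
# rank-scaled stochastic universal sampling, scattered crossover, adaptive
# feasible (bounded Gaussian) mutation, elitism, fixed generation count.

#' Genetic-algorithm configuration
#'
#' @param population Population size (default 200).
#' @param generations Generations to run, with no early stopping
#'   (default 1000).
#' @param mutation_prob Per-gene mutation probability within
#'   mutation-generated offspring (default 0.05).
#' @param crossover_fraction Fraction of non-elite offspring produced by
#'   crossover; the remainder are mutants (default 0.6).
#' @param bounds 2-column matrix (lower, upper) with one row per gene;
#'   defaults to concentration in \[0, 100\] uM and exposure in \[0, 36\] h,
#'   the experimental envelope.
#' @param elite Number of elite individuals copied unchanged each
#'   generation (default `ceiling(0.05 * population)`).
#' @param seed Integer seed; the entire run is deterministic given the
#'   seed, configuration and fitness function.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population = 200, generations = 1000,
                      mutation_prob = 0.05, crossover_fraction = 0.6,
                      bounds = default_ga_bounds(),
                      elite = ceiling(0.05 * population), seed = 1L) {
  check_number(population, "population", lower = 2)
  check_number(generations, "generations", lower = 1)
  check_number(mutation_prob, "mutation_prob", lower = 0, upper = 1)
  check_number(crossover_fraction, "crossover_fraction", lower = 0, upper = 1)
  check_number(elite, "elite", lower = 0, upper = population - 1)
  check_seed(seed)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(!is.finite(bounds)) ||
      any(bounds[, 1] >= bounds[, 2])) {
    stop("bounds must be a finite 2-column (lower, upper) matrix with lower < upper",
         call. = FALSE)
  }
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations),
         mutation_prob = mutation_prob,
         crossover_fraction = crossover_fraction,
         bounds = bounds, elite = as.integer(elite),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Default search bounds
#' @return 2x2 matrix: concentration 0--100 uM, exposure 0--36 h.
#' @export
default_ga_bounds <- function() {
  matrix(c(0, 100, 0, 36), nrow = 2, byrow = TRUE,
         dimnames = list(c("concentration_uM", "exposure_h"),
                         c("lower", "upper")))
}

#' Tetraploid-posterior fitness from a fitted PNN
#'
#' Couples the classifier to the optimizer: fitness of a candidate
#' treatment is the PNN posterior probability of the tetraploid class at
#' that (concentration, exposure) point, evaluated on the standardized
#' scale the model was trained on.
#'
#' @param m A fitted `pnn_model` whose classes include "tetraploid".
#' @param standardizer The `standardizer` fitted on the training features.
#' @return Vectorized fitness function: takes a gene vector or a matrix of
#'   gene rows in original units, returns fitness values in \[0, 1\].
#' @export
make_fitness <- function(m, standardizer) {
  if (!inherits(m, "pnn_model")) stop("`m` must be a fitted pnn_model",
                                      call. = FALSE)
  stopifnot(inherits(standardizer, "standardizer"))
  if (!"tetraploid" %in% m$classes) {
    stop("model has no tetraploid class", call. = FALSE)
  }
  function(genes) {
    g <- as_feature_matrix(genes)
    post <- pnn_posterior(m, apply_standardizer(standardizer, g))
    unname(post[, "tetraploid"])
  }
}

#' Initialize a uniform random population
#'
#' @param cfg A [ga_config()].
#' @return Matrix of `cfg$population` rows, genes i.i.d. uniform over the
#'   bounds rectangle, drawn from the configuration seed.
#' @export
init_population <- function(cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  with_seed(cfg$seed, random_population(cfg$population, cfg$bounds))
}

random_population <- function(n, bounds) {
  d <- nrow(bounds)
  pop <- matrix(stats::runif(n * d), nrow = n)
  pop <- sweep(pop, 2, bounds[, 2] - bounds[, 1], "*")
  sweep(pop, 2, bounds[, 1], "+")
}

#' Rank scaling of fitness values
#'
#' Maps raw fitness to selection weights 1/sqrt(rank) (rank 1 = fittest,
#' ties averaged), making selection pressure independent of the fitness
#' scale. Equal fitnesses receive equal weights.
#'
#' @param fitness Numeric vector of raw fitness values (larger is better).
#' @return Positive weights, one per individual.
#' @export
rank_scale <- function(fitness) {
  r <- rank(-fitness, ties.method = "average")
  1 / sqrt(r)
}

#' Stochastic universal sampling
#'
#' Places `count` evenly spaced pointers with one random phase along the
#' cumulative weight line; each individual's expected selection count is
#' proportional to its weight.
#'
#' @param weights Non-negative selection weights.
#' @param count Number of individuals to draw.
#' @return Integer vector of `count` selected indices (in pointer order).
#' @export
sus_select <- function(weights, count) {
  if (count < 1) stop("count must be >= 1", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  total <- sum(weights)
  step <- total / count
  start <- stats::runif(1, 0, step)
  pointers <- start + step * (seq_len(count) - 1)
  findInterval(pointers, cumsum(weights)) + 1L
}

#' Select parents by rank-scaled stochastic universal sampling
#'
#' @param population Matrix of gene rows.
#' @param fitness Fitness vector aligned with the rows.
#' @param count Number of parents to draw.
#' @return Matrix of `count` selected gene rows, in randomized order so
#'   that consecutive rows can be paired for crossover.
#' @export
select_parents <- function(population, fitness, count) {
  idx <- sus_select(rank_scale(fitness), count)
  idx <- idx[sample.int(length(idx))]
  population[idx, , drop = FALSE]
}

#' Scattered crossover
#'
#' Builds a child by drawing an independent fair binary mask per gene and
#' taking each gene from parent 1 where the mask is 1, else from parent 2.
#'
#' @param p1,p2 Parent gene vectors of equal length.
#' @return Child gene vector (within bounds whenever both parents are).
#' @export
scattered_crossover <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("gene count mismatch", call. = FALSE)
  mask <- stats::runif(length(p1)) < 0.5
  ifelse(mask, p1, p2)
}

#' Adaptive feasible mutation
#'
#' Each gene mutates with probability `cfg$mutation_prob` by adding a
#' Gaussian step with standard deviation `scale` times the gene's bound
#' range; results are clipped to the bounds. The caller contracts `scale`
#' by 0.95 after an unimproved generation and re-expands it by 1/0.95
#' (capped at the initial 0.10) after an improvement.
#'
#' @param ind Gene vector within bounds.
#' @param cfg A [ga_config()].
#' @param scale Step scale as a fraction of each gene's range.
#' @return Mutated gene vector, clipped to bounds.
#' @export
adaptive_feasible_mutation <- function(ind, cfg, scale = 0.10) {
  rng <- cfg$bounds[, 2] - cfg$bounds[, 1]
  hit <- stats::runif(length(ind)) < cfg$mutation_prob
  step <- ifelse(hit, stats::rnorm(length(ind), 0, scale * rng), 0)
  pmin(pmax(ind + step, cfg$bounds[, 1]), cfg$bounds[, 2])
}

#' Run the genetic algorithm
#'
#' Per generation: carry the elites unchanged; fill `crossover_fraction` of
#' the remaining slots with scattered-crossover children of
#' rank-SUS-selected parents and the rest with adaptive-feasible mutants;
#' evaluate; record the best-so-far fitness. Runs exactly
#' `cfg$generations` generations. Elitism makes the best-so-far trace
#' non-decreasing.
#'
#' @param fitness Vectorized fitness function: matrix of gene rows ->
#'   numeric vector (larger is better). All values must be finite.
#' @param cfg A [ga_config()].
#' @return Object of class `ga_result`: list with `best` (gene vector in
#'   original units), `best_fitness`, `trace` (best-so-far per generation),
#'   `generations`, `seed`.
#' @export
evolve <- function(fitness, cfg) {
  stopifnot(is.function(fitness), inherits(cfg, "ga_config"))
  evaluate <- function(pop) {
    f <- as.numeric(fitness(pop))
    if (length(f) != nrow(pop)) {
      stop("fitness must return one value per gene row", call. = FALSE)
    }
    bad <- which(!is.finite(f))
    if (length(bad) > 0) {
      stop("non-finite fitness at gene vector (",
           paste(format(pop[bad[1], ]), collapse = ", "), ")", call. = FALSE)
    }
    f
  }
  with_seed(cfg$seed, {
    init_scale <- 0.10
    scale <- init_scale
    pop <- random_population(cfg$population, cfg$bounds)
    fit <- evaluate(pop)
    best_i <- which.max(fit)
    best <- pop[best_i, ]
    best_fit <- fit[best_i]
    trace <- numeric(cfg$generations)
    n_off <- cfg$population - cfg$elite
    n_x <- round(cfg$crossover_fraction * n_off)
    n_m <- n_off - n_x
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elites <- pop[ord[seq_len(cfg$elite)], , drop = FALSE]
      parents <- select_parents(pop, fit, 2 * n_x + n_m)
      children <- if (n_x > 0) {
        t(vapply(seq_len(n_x), function(i) {
          scattered_crossover(parents[2 * i - 1, ], parents[2 * i, ])
        }, numeric(ncol(pop))))
      } else matrix(numeric(0), 0, ncol(pop))
      mutants <- if (n_m > 0) {
        base <- parents[2 * n_x + seq_len(n_m), , drop = FALSE]
        t(vapply(seq_len(n_m), function(i) {
          adaptive_feasible_mutation(base[i, ], cfg, scale)
        }, numeric(ncol(pop))))
      } else matrix(numeric(0), 0, ncol(pop))
      pop <- rbind(elites, children, mutants)
      fit <- evaluate(pop)
      gen_best <- which.max(fit)
      improved <- fit[gen_best] > best_fit
      if (improved) {
        best_fit <- fit[gen_best]
        best <- pop[gen_best, ]
      }
      scale <- if (improved) min(scale / 0.95, init_scale) else scale * 0.95
      trace[gen] <- best_fit
    }
    structure(
      list(best = stats::setNames(best, rownames(cfg$bounds)),
           best_fitness = best_fit, trace = trace,
           generations = cfg$generations, seed = cfg$seed),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> best fitness", format(x$best_fitness, digits = 6),
      "after", x$generations, "generations\n")
  cat("  optimum:", paste(sprintf("%s = %.2f", names(x$best), x$best),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive grid search over the fitness surface
#'
#' Independent reference optimizer: evaluates the fitness on a regular
#' `n x n` grid over the bounds and returns the argmax. Used to check that
#' the genetic algorithm attains the surface optimum.
#'
#' @param fitness Vectorized fitness function, as in [evolve()].
#' @param bounds Bounds matrix, as in [ga_config()].
#' @param n Grid resolution per gene (default 200).
#' @return List with `best` (gene vector) and `best_fitness`.
#' @export
grid_argmax <- function(fitness, bounds = default_ga_bounds(), n = 200) {
  axes <- lapply(seq_len(nrow(bounds)), function(i) {
    seq(bounds[i, 1], bounds[i, 2], length.out = n)
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- rownames(bounds)
  f <- as.numeric(fitness(grid))
  i <- which.max(f)
  list(best = grid[i, ], best_fitness = f[i])
}
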