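#' Genetic-algorithm configuration
#'
#' Defaults follow the settings found best by grid search for this class of
#' retention data: population 20, crossover fraction 0.8, mutation rate
#' 0.2, 2 elites, at most 100 generations with a stall limit of 10
#' generations without any change in the best RMSECV, tournament selection
#' of size 2, and at least 2 latent variables per candidate model.
#'
#' @param population_size Number of binary masks per generation.
#' @param crossover_fraction Fraction of the non-elite offspring produced
#'   by single-point crossover; the remainder are cloned from a tournament
#'   winner and mutated bit-wise.
#' @param mutation_rate Per-bit flip probability for mutation offspring.
#' @param elite_count Elites copied unchanged each generation.
#' @param max_generations Hard generation cap.
#' @param stall_limit Stop after this many consecutive generations without
#'   a change (tolerance 1e-12) in best RMSECV.
#' @param tournament_size Candidates per tournament.
#' @param lv_min Lower bound of the latent-variable search inside the
#'   fitness (candidates `lv_min..rank` of the subset).
#' @param seed Optional integer seed making the run reproducible.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20, crossover_fraction = 0.8,
                      mutation_rate = 0.2, elite_count = 2,
                      max_generations = 100, stall_limit = 10,
                      tournament_size = 2, lv_min = 2, seed = NULL) {
  stopifnot(population_size >= 2,
            crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elite_count >= 0, elite_count < population_size,
            max_generations >= 1, stall_limit >= 1,
            tournament_size >= 1, lv_min >= 1)
  structure(list(population_size = as.integer(population_size),
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 max_generations = as.integer(max_generations),
                 stall_limit = as.integer(stall_limit),
                 tournament_size = as.integer(tournament_size),
                 lv_min = as.integer(lv_min),
                 seed = seed), class = "ga_config")
}

#' Fitness cache for memoized mask evaluations
#'
#' Shared across GA runs on the same dataset: the LOO-CV fitness of a mask
#' is deterministic, so repeated runs reuse each other's evaluations.
#' `hits`/`misses` counters expose cache behaviour.
#'
#' @return Environment with a `map` environment and counters.
#' @export
new_fitness_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(hash = TRUE, parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  e
}

#' GA fitness: LOO-CV RMSECV of a descriptor subset
#'
#' The fitness of a binary mask is the minimum leave-one-out RMSECV of the
#' SIMPLS model on the selected submatrix, with the number of latent
#' variables optimized over `lv_min..rank` inside the evaluation. Masks
#' selecting fewer than two descriptors receive an infinite sentinel
#' fitness (never an error) so evolution can continue past them.
#'
#' @param mask Binary (0/1) vector of length p.
#' @param X Descriptor matrix.
#' @param y ln-retention response.
#' @param lv_min Lower bound of the LV search (default 2).
#' @param cache Optional [new_fitness_cache()] for memoization.
#' @return List with `rmsecv` and the chosen `n_lv` (`NA` for penalized
#'   masks).
#' @export
ga_fitness <- function(mask, X, y, lv_min = 2, cache = NULL) {
  key <- paste(as.integer(mask), collapse = "")
  if (!is.null(cache)) {
    hit <- get0(key, envir = cache$map, inherits = FALSE)
    if (!is.null(hit)) {
      cache$hits <- cache$hits + 1L
      return(hit)
    }
  }
  sel <- which(mask != 0)
  if (length(sel) < 2) {
    out <- list(rmsecv = Inf, n_lv = NA_integer_)
  } else {
    Xs <- X[, sel, drop = FALSE]
    pred <- loocv_predictions_core(Xs, y, length(sel))
    rms <- sqrt(colMeans((pred - y)^2))
    lo <- min(lv_min, length(rms))
    idx <- seq(lo, length(rms))
    best <- idx[which.min(rms[idx])]
    out <- list(rmsecv = rms[best], n_lv = as.integer(best))
  }
  if (!is.null(cache)) {
    assign(key, out, envir = cache$map)
    cache$misses <- cache$misses + 1L
  }
  out
}

tournament_pick <- function(fit_values, size) {
  cand <- sample.int(length(fit_values), size, replace = TRUE)
  cand[which.min(fit_values[cand])] # ties: first drawn wins
}

#' Evolve a binary descriptor-selection GA
#'
#' Uniform random initial population (inclusion probability 0.5 per bit),
#' tournament selection, single-point crossover on a fraction of the
#' non-elite offspring, bit-wise uniform mutation on the remainder, and
#' elitism. Stops at `max_generations` or once the best RMSECV has not
#' changed for `stall_limit` consecutive generations. Fully reproducible
#' from `config$seed`.
#'
#' @param X Descriptor matrix (m x p, p >= 2, m >= 3).
#' @param y ln-retention response.
#' @param config A [ga_config()].
#' @param cache Optional shared [new_fitness_cache()].
#' @return Object of class `ga_run`: `best_mask`, `best_rmsecv`, `n_lv`,
#'   `generations_run`, `trajectory` (best RMSECV per generation), `seed`.
#' @export
ga_evolve <- function(X, y, config = ga_config(), cache = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2 || nrow(X) < 3) stop("need p >= 2 descriptors and m >= 3 analytes")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(cache)) cache <- new_fitness_cache()
  evalmask <- function(mk) ga_fitness(mk, X, y, lv_min = config$lv_min,
                                      cache = cache)
  np <- config$population_size
  pop <- matrix(as.integer(stats::runif(np * p) < 0.5), nrow = np, ncol = p)
  fits <- lapply(seq_len(np), function(i) evalmask(pop[i, ]))
  fvals <- vapply(fits, `[[`, numeric(1), "rmsecv")
  best_val <- Inf
  best_i <- which.min(fvals)
  trajectory <- numeric(0)
  stall <- 0L
  gen <- 0L
  n_elite <- config$elite_count
  n_off <- np - n_elite
  n_cross <- round(config$crossover_fraction * n_off)
  repeat {
    gen <- gen + 1L
    gen_best <- min(fvals)
    if (is.finite(best_val) && abs(gen_best - best_val) <= 1e-12) {
      stall <- stall + 1L
    } else {
      stall <- if (gen_best < best_val) 0L else stall + 1L
    }
    best_val <- min(best_val, gen_best)
    trajectory <- c(trajectory, best_val)
    if (gen >= config$max_generations || stall >= config$stall_limit) break
    ord <- order(fvals)
    elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    children <- matrix(0L, nrow = n_off, ncol = p)
    for (k in seq_len(n_off)) {
      if (k <= n_cross) {
        p1 <- pop[tournament_pick(fvals, config$tournament_size), ]
        p2 <- pop[tournament_pick(fvals, config$tournament_size), ]
        cut <- if (p > 1) sample.int(p - 1, 1) else 1L
        children[k, ] <- c(p1[seq_len(cut)], p2[seq(cut + 1, p)])
      } else {
        ch <- pop[tournament_pick(fvals, config$tournament_size), ]
        flip <- stats::runif(p) < config$mutation_rate
        ch[flip] <- 1L - ch[flip]
        children[k, ] <- ch
      }
    }
    pop <- rbind(elites, children)
    fits <- lapply(seq_len(np), function(i) evalmask(pop[i, ]))
    fvals <- vapply(fits, `[[`, numeric(1), "rmsecv")
  }
  best_i <- which.min(fvals)
  # the overall best is always present in the population through elitism
  structure(list(best_mask = unname(pop[best_i, ]),
                 best_rmsecv = fvals[best_i],
                 n_lv = fits[[best_i]]$n_lv,
                 generations_run = gen,
                 trajectory = trajectory,
                 seed = config$seed), class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat("GA run:", sum(x$best_mask), "descriptors selected, RMSECV =",
      signif(x$best_rmsecv, 4), "(", x$n_lv, "LVs,",
      x$generations_run, "generations )\n")
  invisible(x)
}

#' Grid search over GA hyper-parameters
#'
#' Evaluates every (population size, crossover fraction, mutation rate)
#' cell by running the GA and comparing best RMSECV values; returns the
#' winning configuration and the full grid table.
#'
#' @param X,y Data as in [ga_evolve()].
#' @param population_sizes,crossover_fractions,mutation_rates Grid axes.
#' @param config Base [ga_config()] providing the remaining settings.
#' @param seed Seed reused for every cell so cells differ only in the
#'   hyper-parameters.
#' @return List with `best_config`, `best_rmsecv` and `grid` (data frame
#'   of every cell).
#' @export
ga_grid_search <- function(X, y, population_sizes = c(10, 20),
                           crossover_fractions = seq(0.1, 0.8, by = 0.1),
                           mutation_rates = seq(0.1, 0.8, by = 0.1),
                           config = ga_config(), seed = 1) {
  grid <- expand.grid(population_size = population_sizes,
                      crossover_fraction = crossover_fractions,
                      mutation_rate = mutation_rates)
  if (!nrow(grid)) stop("empty hyper-parameter grid")
  cache <- new_fitness_cache()
  grid$rmsecv <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$population_size <- as.integer(grid$population_size[i])
    cfg$crossover_fraction <- grid$crossover_fraction[i]
    cfg$mutation_rate <- grid$mutation_rate[i]
    cfg$seed <- seed + i - 1
    grid$rmsecv[i] <- ga_evolve(X, y, cfg, cache = cache)$best_rmsecv
  }
  best <- which.min(grid$rmsecv)
  cfg <- config
  cfg$population_size <- as.integer(grid$population_size[best])
  cfg$crossover_fraction <- grid$crossover_fraction[best]
  cfg$mutation_rate <- grid$mutation_rate[best]
  list(best_config = cfg, best_rmsecv = grid$rmsecv[best], grid = grid)
}
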