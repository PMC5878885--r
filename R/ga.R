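# Genetic algorithm over specification masks: tournament selection, uniform
# crossover, bit-flip mutation, (mu + lambda) elitist retention, plus an
# exhaustive-search oracle for small n.

#' Genetic algorithm configuration
#'
#' Defaults are the control parameters used throughout the package:
#' population size 40, 100 generations, tournament size 3, crossover rate
#' 0.6, mixing ratio 0.2, mutation rate 0.2, bit-flip rate 0.05. Fitness is
#' the 5-fold cross-validated AUC under `mode`, with one `fold_seed` shared
#' by every candidate evaluation so fitness is a pure function of the mask.
#'
#' @param population_size number of candidate masks `N` (default 40).
#' @param generations number of generations (default 100).
#' @param tournament_k tournament size (default 3).
#' @param crossover_rate probability a selected pair is crossed (default 0.6).
#' @param mixing_ratio per-bit exchange probability in uniform crossover
#'   (default 0.2).
#' @param mutation_rate probability an offspring is mutated (default 0.2).
#' @param bit_flip_rate per-bit inversion probability within a mutated
#'   offspring (default 0.05).
#' @param mode `"flattened"` or `"hierarchical"` fitness.
#' @param k_folds CV folds (default 5).
#' @param rng_seed seed driving all GA randomness.
#' @param fold_seed seed fixing the CV fold assignment.
#' @param ridge ridge penalty for the logistic fits.
#' @param hof_size hall-of-fame size `M`, the number of top distinct masks
#'   retained for stability analysis (default 20).
#' @return A validated `ga_config` list.
#' @export
ga_config <- function(population_size = 40L, generations = 100L,
                      tournament_k = 3L, crossover_rate = 0.6,
                      mixing_ratio = 0.2, mutation_rate = 0.2,
                      bit_flip_rate = 0.05,
                      mode = c("flattened", "hierarchical"),
                      k_folds = 5L, rng_seed = 1L, fold_seed = 1L,
                      ridge = 1e-6, hof_size = 20L) {
  mode <- match.arg(mode)
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              tournament_k = as.integer(tournament_k),
              crossover_rate = crossover_rate, mixing_ratio = mixing_ratio,
              mutation_rate = mutation_rate, bit_flip_rate = bit_flip_rate,
              mode = mode, k_folds = as.integer(k_folds),
              rng_seed = as.integer(rng_seed),
              fold_seed = as.integer(fold_seed), ridge = ridge,
              hof_size = as.integer(hof_size))
  probs <- c(crossover_rate, mixing_ratio, mutation_rate, bit_flip_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_evospec("rates and ratios must be probabilities in [0, 1]",
                 "evospec_validation_error")
  }
  if (cfg$population_size < 2L) {
    stop_evospec("population_size must be at least 2",
                 "evospec_validation_error")
  }
  if (cfg$tournament_k < 1L || cfg$tournament_k > cfg$population_size) {
    stop_evospec("tournament_k must be in [1, population_size]",
                 "evospec_validation_error")
  }
  if (cfg$generations < 0L) {
    stop_evospec("generations must be non-negative",
                 "evospec_validation_error")
  }
  structure(cfg, class = "ga_config")
}

#' Random initial population of specification masks
#'
#' Each of the `N` masks has every bit drawn as an independent fair coin
#' from the current RNG stream.
#'
#' @param n mask length (number of specific complaints).
#' @param N population size.
#' @return An `N x n` integer 0/1 matrix, one mask per row.
#' @export
init_population <- function(n, N) {
  stopifnot(n >= 1L, N >= 2L)
  matrix(sample(c(0L, 1L), n * N, replace = TRUE), nrow = N, ncol = n)
}

#' Tournament selection of one parent mask
#'
#' Draws `k` members uniformly with replacement and returns the one with
#' maximal fitness; exact fitness ties are broken uniformly at random.
#'
#' @param population mask matrix (individuals in rows).
#' @param fitnesses fitness vector aligned with rows.
#' @param k tournament size.
#' @return One mask (integer vector).
#' @export
tournament_select <- function(population, fitnesses, k) {
  N <- nrow(population)
  if (is.null(N) || N == 0L) {
    stop_evospec("population is empty", "evospec_validation_error")
  }
  entrants <- sample.int(N, k, replace = TRUE)
  best <- entrants[fitnesses[entrants] == max(fitnesses[entrants])]
  winner <- if (length(best) == 1L) best else sample(best, 1L)
  population[winner, ]
}

#' Uniform crossover of two parent masks
#'
#' Independently at each bit position, with probability `mixing_ratio` the
#' two parents' bits are exchanged between the children; otherwise both
#' children inherit the bit unchanged. Uniform crossover suits this search
#' because selected complaints are essentially independent of one another,
#' so there are no contiguous blocks worth preserving.
#'
#' @param parent_a,parent_b equal-length binary masks.
#' @param mixing_ratio per-bit exchange probability.
#' @return List with `child_a` and `child_b`.
#' @export
uniform_crossover <- function(parent_a, parent_b, mixing_ratio) {
  if (length(parent_a) != length(parent_b)) {
    stop_evospec("parents must have equal length", "evospec_validation_error")
  }
  swap <- runif(length(parent_a)) < mixing_ratio
  child_a <- parent_a
  child_b <- parent_b
  child_a[swap] <- parent_b[swap]
  child_b[swap] <- parent_a[swap]
  list(child_a = child_a, child_b = child_b)
}

#' Bit-flip mutation of a mask
#'
#' Each bit is independently inverted with probability `bit_flip_rate`:
#' excluded complaints picked for mutation become selected and vice versa.
#'
#' @param mask binary mask.
#' @param bit_flip_rate per-bit inversion probability.
#' @return The mutated mask.
#' @export
bit_flip_mutate <- function(mask, bit_flip_rate) {
  flip <- runif(length(mask)) < bit_flip_rate
  mask[flip] <- 1L - mask[flip]
  mask
}

# Memoizing fitness evaluator. `cache` maps mask string -> fitness; valid
# because the shared fold_seed makes fitness a pure function of the mask.
make_evaluator <- function(cohort, config, cache, fitness_fn = NULL) {
  if (is.null(fitness_fn)) {
    fitness_fn <- function(mask) {
      cv_auc_fast(cohort, mask, config$mode, k = config$k_folds,
                  fold_seed = config$fold_seed, ridge = config$ridge)
    }
  }
  misses <- 0L
  calls <- 0L
  evaluate <- function(masks) {
    vapply(seq_len(nrow(masks)), function(i) {
      key <- mask_key(masks[i, ])
      calls <<- calls + 1L
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- fitness_fn(masks[i, ])
        cache[[key]] <- hit
        misses <<- misses + 1L
      }
      hit
    }, numeric(1))
  }
  list(evaluate = evaluate,
       misses = function() misses, calls = function() calls)
}

#' Run the genetic algorithm search over specification masks
#'
#' Implements a (mu + lambda) generational scheme with lambda = N: each
#' generation, N offspring are produced by tournament selection and pairwise
#' uniform crossover (each pair crossed with probability `crossover_rate`),
#' each offspring is mutated with probability `mutation_rate` (bit flips at
#' `bit_flip_rate`), and the top N of parents plus offspring are retained.
#' Retention ranks by fitness descending, breaking ties toward fewer
#' selected bits and then lexicographically, so runs are fully reproducible
#' from `(rng_seed, fold_seed)`. Mutation touches offspring only; surviving
#' parents are never perturbed, which together with elitist retention makes
#' the best fitness non-decreasing across generations.
#'
#' @param cohort an `ed_cohort`.
#' @param config a [ga_config()].
#' @param cache optional environment memoizing mask fitness across runs that
#'   share the same cohort, mode and fold seed.
#' @param fitness_fn optional replacement fitness function `mask -> scalar`
#'   (must be deterministic); defaults to [cv_fitness()] under `config`.
#' @return A `ga_result`: `best_mask`, `best_fitness`, per-generation
#'   `history` (best/mean), `hall_of_fame` (top-M distinct masks with
#'   fitness), `evaluations` (fitness computations performed),
#'   `fitness_calls` (including cache hits) and the `config` echo.
#' @export
evolve <- function(cohort, config, cache = NULL, fitness_fn = NULL) {
  stopifnot(inherits(config, "ga_config"))
  n <- n_complaints(cohort$hierarchy)
  N <- config$population_size
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ev <- make_evaluator(cohort, config, cache, fitness_fn)
  seen <- new.env(parent = emptyenv())
  note_seen <- function(masks, fits) {
    for (i in seq_len(nrow(masks))) seen[[mask_key(masks[i, ])]] <- fits[i]
  }

  with_seed(config$rng_seed, {
    pop <- init_population(n, N)
    fits <- ev$evaluate(pop)
    note_seen(pop, fits)
    ord <- rank_candidates(fits, rowSums(pop),
                           apply(pop, 1L, mask_key))
    pop <- pop[ord, , drop = FALSE]
    fits <- fits[ord]
    history <- data.frame(generation = 0L, best = fits[1L],
                          mean = mean(fits))

    for (gen in seq_len(config$generations)) {
      offspring <- matrix(0L, nrow = N, ncol = n)
      i <- 1L
      while (i <= N) {
        p1 <- tournament_select(pop, fits, config$tournament_k)
        if (i == N) {
          offspring[i, ] <- p1
          i <- i + 1L
          break
        }
        p2 <- tournament_select(pop, fits, config$tournament_k)
        if (runif(1L) < config$crossover_rate) {
          ch <- uniform_crossover(p1, p2, config$mixing_ratio)
          offspring[i, ] <- ch$child_a
          offspring[i + 1L, ] <- ch$child_b
        } else {
          offspring[i, ] <- p1
          offspring[i + 1L, ] <- p2
        }
        i <- i + 2L
      }
      mutate <- runif(N) < config$mutation_rate
      for (j in which(mutate)) {
        offspring[j, ] <- bit_flip_mutate(offspring[j, ],
                                          config$bit_flip_rate)
      }
      off_fits <- tryCatch(ev$evaluate(offspring), error = function(e) {
        stop_evospec(sprintf("generation %d: %s", gen, conditionMessage(e)),
                     class(e)[1L])
      })
      note_seen(offspring, off_fits)
      comb <- rbind(pop, offspring)
      comb_fits <- c(fits, off_fits)
      keys <- apply(comb, 1L, mask_key)
      ord <- rank_candidates(comb_fits, rowSums(comb), keys)
      # retain the top N DISTINCT candidates (duplicates only if there are
      # not N distinct masks): clones of the leaders otherwise crowd out
      # diversity and stall the search on plateaus
      distinct <- ord[!duplicated(keys[ord])]
      ord <- c(distinct, setdiff(ord, distinct))[seq_len(N)]
      pop <- comb[ord, , drop = FALSE]
      fits <- comb_fits[ord]
      history <- rbind(history,
                       data.frame(generation = gen, best = fits[1L],
                                  mean = mean(fits)))
    }

    keys <- ls(seen)
    seen_fits <- vapply(keys, function(k) seen[[k]], numeric(1))
    nbits <- vapply(keys, function(k) {
      sum(utf8ToInt(k) == utf8ToInt("1"))
    }, numeric(1))
    top <- rank_candidates(seen_fits, nbits, keys)
    top <- top[seq_len(min(config$hof_size, length(top)))]
    hof_masks <- do.call(rbind, lapply(keys[top], function(k) {
      as.integer(strsplit(k, "")[[1L]])
    }))

    structure(
      list(best_mask = pop[1L, ], best_fitness = fits[1L],
           history = history,
           hall_of_fame = list(masks = hof_masks,
                               fitness = unname(seen_fits[top])),
           evaluations = ev$misses(), fitness_calls = ev$calls(),
           config = config),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(paste0(
    "GA result (%s): best CV-AUC %.4f with %d/%d complaints selected\n",
    "  %d generations, %d fitness evaluations (%d calls incl. cache hits)\n"),
    x$config$mode, x$best_fitness, sum(x$best_mask), length(x$best_mask),
    max(x$history$generation), x$evaluations, x$fitness_calls))
  invisible(x)
}

#' Exhaustive evaluation of every specification mask (small-n oracle)
#'
#' Evaluates all `2^n` masks with [cv_fitness()]; deterministic. Intended as
#' a ground-truth check for the stochastic search on small hierarchies.
#'
#' @param cohort an `ed_cohort`.
#' @param mode `"flattened"` or `"hierarchical"`.
#' @param k_folds,fold_seed,ridge as in [cv_fitness()].
#' @param max_n refusal cap on `n` (default 16).
#' @param cache optional memoization environment shared with [evolve()].
#' @param fitness_fn optional replacement fitness function.
#' @return List with `best_mask`, `best_fitness` and `table` (a data frame
#'   of all masks, as 0/1 strings, with fitness).
#' @export
exhaustive_search <- function(cohort, mode = c("flattened", "hierarchical"),
                              k_folds = 5L, fold_seed = 1L, ridge = 1e-6,
                              max_n = 16L, cache = NULL, fitness_fn = NULL) {
  mode <- match.arg(mode)
  n <- n_complaints(cohort$hierarchy)
  if (n > max_n) {
    stop_evospec(sprintf(
      "refusing exhaustive search: n = %d exceeds the cap max_n = %d (2^n masks)",
      n, max_n), "evospec_domain_error")
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  config <- list(mode = mode, k_folds = k_folds, fold_seed = fold_seed,
                 ridge = ridge)
  ev <- make_evaluator(cohort, config, cache, fitness_fn)
  masks <- matrix(0L, nrow = 2L^n, ncol = n)
  for (i in seq_len(2L^n)) {
    masks[i, ] <- as.integer(intToBits(i - 1L))[seq_len(n)]
  }
  fits <- ev$evaluate(masks)
  keys <- apply(masks, 1L, mask_key)
  ord <- rank_candidates(fits, rowSums(masks), keys)
  list(best_mask = masks[ord[1L], ], best_fitness = fits[ord[1L]],
       table = data.frame(mask = keys, fitness = fits,
                          stringsAsFactors = FALSE))
}
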