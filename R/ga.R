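#' Genetic-algorithm configuration
#'
#' Hyperparameters of the binary-chromosome GA used for variable subset
#' search.  Defaults follow common small-p GA-PLS practice: population 30,
#' 100 generations, single-point crossover with probability 0.5, bit-flip
#' mutation rate 0.01, elitism of 1, fitness from an inner 5-fold
#' cross-validation, 5 independent runs aggregated by inclusion frequency
#' with cutoff 0.6.
#'
#' @param population_size,n_generations GA population and generation counts.
#' @param crossover_prob,mutation_prob Crossover / per-gene mutation
#'   probabilities in `[0, 1]`.
#' @param fitness_cv_folds Folds of the inner cross-validation defining
#'   fitness.
#' @param n_runs Independent GA replicates.
#' @param inclusion_frequency_cutoff Fraction of runs whose best chromosome
#'   must include a variable for it to enter the final mask.
#' @param max_lv Cap on latent variables tried by the inner CV.
#' @param elite Number of elite individuals copied unchanged each
#'   generation.
#' @param seed Master seed; run `r` uses `seed + r - 1`.
#' @param initial_population Optional 0/1 matrix (population x p) seeding
#'   every run's population.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, n_generations = 100L,
                      crossover_prob = 0.5, mutation_prob = 0.01,
                      fitness_cv_folds = 5L, n_runs = 5L,
                      inclusion_frequency_cutoff = 0.6, max_lv = 10L,
                      elite = 1L, seed = 1L, initial_population = NULL) {
  stopifnot(is_count(population_size), is_count(n_generations),
            is_count(fitness_cv_folds), is_count(n_runs), is_count(max_lv),
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            inclusion_frequency_cutoff >= 0,
            inclusion_frequency_cutoff <= 1,
            is_count(elite + 1L))  # elite may be 0
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 fitness_cv_folds = as.integer(fitness_cv_folds),
                 n_runs = as.integer(n_runs),
                 inclusion_frequency_cutoff = inclusion_frequency_cutoff,
                 max_lv = as.integer(max_lv), elite = as.integer(elite),
                 seed = seed, initial_population = initial_population),
            class = "ga_config")
}

#' Genetic-algorithm variable selection for PLSR
#'
#' Searches variable subsets with a binary-chromosome genetic algorithm
#' (one gene per variable).  Fitness of a chromosome is the negative RMSECV
#' of a SIMPLS model on its variables, with the latent-variable count chosen
#' by the same inner cross-validation (folds drawn once per run so fitness
#' values are comparable).  Tournament selection, single-point crossover,
#' bit-flip mutation and elitism drive the search; the all-zero chromosome
#' gets the worst possible fitness.  `n_runs` independent replicates are
#' aggregated: the final mask keeps variables included in at least
#' `inclusion_frequency_cutoff` of the runs' best chromosomes, and the
#' reported scores are those inclusion frequencies.  Variables with zero
#' variance are excluded from the search.
#'
#' @param X Calibration predictor matrix (raw units), p >= 2 columns.
#' @param y Response vector.
#' @param cfg A [ga_config()].
#' @return A `selection_result` with `method = "GA"`; attribute
#'   `elite_fitness` holds the per-run trajectory of the best fitness
#'   (non-decreasing under elitism) and attribute `best_chromosomes` the
#'   per-run winning masks.
#' @export
ga_select <- function(X, y, cfg = ga_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop_("GA selection needs at least 2 variables")
  eligible <- nonconstant_cols(X)
  if (!any(eligible)) stop_("no variable has nonzero variance")

  fitness_of <- function(chrom, folds, cache) {
    key <- paste0("k", paste(which(chrom), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (!any(chrom)) -Inf else {
      cv <- suppressWarnings(
        kfold_cv(X[, chrom, drop = FALSE], y,
                 A_max = min(cfg$max_lv, sum(chrom)), folds = folds))
      -min(cv$rmsecv_by_A)
    }
    cache[[key]] <- val
    val
  }

  run_once <- function() {
    folds <- sample(rep(seq_len(cfg$fitness_cv_folds), length.out = n))
    cache <- new.env(parent = emptyenv())
    pop <- if (!is.null(cfg$initial_population)) {
      stopifnot(ncol(cfg$initial_population) == p)
      matrix(as.logical(cfg$initial_population),
             nrow = nrow(cfg$initial_population))
    } else {
      matrix(runif(cfg$population_size * p) < 0.5,
             nrow = cfg$population_size)
    }
    pop[, !eligible] <- FALSE
    fit <- apply(pop, 1L, fitness_of, folds = folds, cache = cache)
    elite_trace <- numeric(cfg$n_generations + 1L)
    elite_trace[1L] <- max(fit)
    for (g in seq_len(cfg$n_generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(FALSE, nrow(pop), p)
      n_elite <- min(cfg$elite, nrow(pop))
      if (n_elite > 0L)
        newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ,
                                          drop = FALSE]
      for (i in seq_len(nrow(pop) - n_elite)) {
        pick <- function() {           # tournament of 2
          cand <- sample.int(nrow(pop), 2L)
          cand[which.max(fit[cand])]
        }
        pa <- pop[pick(), ]; pb <- pop[pick(), ]
        child <- if (runif(1L) < cfg$crossover_prob && p > 1L) {
          cut <- sample.int(p - 1L, 1L)
          c(pa[seq_len(cut)], pb[(cut + 1L):p])
        } else pa
        flip <- runif(p) < cfg$mutation_prob
        child <- xor(child, flip)
        child[!eligible] <- FALSE
        newpop[n_elite + i, ] <- child
      }
      pop <- newpop
      fit <- apply(pop, 1L, fitness_of, folds = folds, cache = cache)
      elite_trace[g + 1L] <- max(fit)
    }
    best <- which.max(fit)
    list(chrom = pop[best, ], trace = elite_trace)
  }

  runs <- lapply(seq_len(cfg$n_runs), function(r)
    withr::with_seed(child_seed(cfg$seed, r - 1L), run_once()))
  best_mat <- do.call(rbind, lapply(runs, `[[`, "chrom"))
  freq <- colMeans(best_mat)
  names(freq) <- colnames(X)
  mask <- freq >= cfg$inclusion_frequency_cutoff
  out <- selection_result("GA", freq, cfg$inclusion_frequency_cutoff, mask)
  attr(out, "elite_fitness") <- lapply(runs, `[[`, "trace")
  attr(out, "best_chromosomes") <- best_mat
  out
}
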