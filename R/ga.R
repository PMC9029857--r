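#' Genetic-algorithm configuration
#'
#' Defaults are the canonical search settings: 80 solutions per
#' generation, 200 generations, bitwise mutation threshold 0.1 on the first
#' half of the population (the second half always receives exactly one
#' random bit flip), one-point crossover threshold 0.5, and 10 repeated
#' runs per fitness measure.
#'
#' @param population_size Even number of chromosomes per generation (>= 4).
#' @param generations Number of generations per run.
#' @param mutation_threshold Per-bit flip probability for the first half of
#'   the population, in \[0, 1\].
#' @param crossover_threshold Probability that a chromosome pair undergoes
#'   one-point crossover, in \[0, 1\].
#' @param repeats Independent GA runs per fitness measure.
#' @param seed Master seed; every random draw in the run derives from it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 80, generations = 200,
                      mutation_threshold = 0.1, crossover_threshold = 0.5,
                      repeats = 10, seed = 1) {
  assert_count(population_size, "population_size", min = 4L)
  if (population_size %% 2L != 0L) stopf("`population_size` must be even")
  assert_count(generations, "generations", min = 1L)
  assert_count(repeats, "repeats", min = 1L)
  for (nm in c("mutation_threshold", "crossover_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stopf("`%s` must be in [0, 1]", nm)
    }
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_threshold = mutation_threshold,
                 crossover_threshold = crossover_threshold,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "ga_config")
}

#' Random initial population
#'
#' Each bit is drawn i.i.d. Bernoulli(0.5); all-zero chromosomes are
#' redrawn (an empty gene subset has no defined classifier). Draws from the
#' current RNG state — callers seed it ([run_ga()] does so from its
#' config).
#'
#' @param cfg A [ga_config()].
#' @param n_bits Chromosome length (the candidate-panel size).
#' @return Integer 0/1 matrix, `population_size` x `n_bits`.
#' @export
init_population <- function(cfg, n_bits) {
  assert_count(n_bits, "n_bits", min = 1L)
  pop <- matrix(sample(c(0L, 1L), cfg$population_size * n_bits, replace = TRUE),
                cfg$population_size, n_bits)
  for (i in seq_len(nrow(pop))) {
    while (sum(pop[i, ]) == 0L) {
      pop[i, ] <- sample(c(0L, 1L), n_bits, replace = TRUE)
    }
  }
  pop
}

# Elite state: alpha/beta carried across generations, each a list of
# (bits, fitness); fitness 0 before the first generation.
new_elite_state <- function(n_bits) {
  virt <- list(bits = integer(n_bits), fitness = 0, virtual = TRUE)
  list(alpha = virt, beta = virt)
}

#' Elitist selection
#'
#' The population is split in halves. The first-half elite is the best of
#' the current first half and the previous first-half elite; likewise for
#' the second half. The generation's best solution is the better of the
#' two elites. The next population is filled with copies: odd positions
#' (1-based) take the first-half elite, even positions the second-half
#' elite. Ties resolve to the lowest index, and previous elites win ties
#' against current chromosomes, so the procedure is deterministic and the
#' best-so-far fitness never decreases.
#'
#' @param population 0/1 chromosome matrix (rows = chromosomes).
#' @param fitnesses Fitness per row of `population`.
#' @param state Elite state from a previous call, or `NULL` at the first
#'   generation (previous elites then have fitness 0).
#' @return List with `population` (the copied next generation), `state`
#'   (updated elites) and `omega` (the generation-best record:
#'   `bits`, `fitness`).
#' @export
select_elites <- function(population, fitnesses, state = NULL) {
  n <- nrow(population)
  if (length(fitnesses) != n) stopf("one fitness per chromosome required")
  if (is.null(state)) state <- new_elite_state(ncol(population))
  half <- n %/% 2L

  pick <- function(rows, prev) {
    best <- rows[which.max(fitnesses[rows])]  # lowest index on ties
    # a real previous elite wins ties; the virtual pre-run elite (fitness
    # defined as 0, empty chromosome) loses them so it cannot propagate
    beats <- fitnesses[best] > prev$fitness ||
      (isTRUE(prev$virtual) && fitnesses[best] >= prev$fitness)
    if (beats) {
      list(bits = population[best, ], fitness = fitnesses[best],
           virtual = FALSE)
    } else {
      prev
    }
  }
  alpha <- pick(seq_len(half), state$alpha)
  beta <- pick(seq.int(half + 1L, n), state$beta)
  omega <- if (alpha$fitness >= beta$fitness) alpha else beta

  nxt <- matrix(0L, n, ncol(population))
  odd <- seq(1L, n, by = 2L)
  nxt[odd, ] <- rep(alpha$bits, each = length(odd))
  nxt[-odd, ] <- rep(beta$bits, each = n - length(odd))
  list(population = nxt, state = list(alpha = alpha, beta = beta),
       omega = omega)
}

#' Dual-scheme mutation
#'
#' First half of the population: every bit flips independently with
#' probability `mutation_threshold`. Second half: exactly one uniformly
#' chosen bit flips per chromosome. Draws from the current RNG state.
#'
#' @param population 0/1 chromosome matrix.
#' @param mutation_threshold Per-bit flip probability for the first half.
#' @return Mutated population matrix.
#' @export
mutate_population <- function(population, mutation_threshold = 0.1) {
  n <- nrow(population)
  l <- ncol(population)
  half <- n %/% 2L
  if (half > 0L) {
    flips <- matrix(runif(half * l) < mutation_threshold, half, l)
    first <- population[seq_len(half), , drop = FALSE]
    first[flips] <- 1L - first[flips]
    population[seq_len(half), ] <- first
  }
  for (i in seq.int(half + 1L, n)) {
    b <- sample.int(l, 1L)
    population[i, b] <- 1L - population[i, b]
  }
  population
}

#' One-point crossover
#'
#' For each consecutive pair (1,2), (3,4), ...: with probability
#' `crossover_threshold`, a cut point `lambda` is drawn uniformly from
#' 1..L and positions `lambda..L` of the two chromosomes are swapped.
#' Draws from the current RNG state.
#'
#' @param population 0/1 chromosome matrix with an even number of rows.
#' @param crossover_threshold Per-pair crossover probability.
#' @return Recombined population matrix.
#' @export
crossover_population <- function(population, crossover_threshold = 0.5) {
  n <- nrow(population)
  if (n %% 2L != 0L) stopf("population size must be even for pairing")
  l <- ncol(population)
  for (k in seq_len(n %/% 2L)) {
    i <- 2L * k - 1L
    if (runif(1) < crossover_threshold) {
      lambda <- sample.int(l, 1L)
      seg <- seq.int(lambda, l)
      tmp <- population[i, seg]
      population[i, seg] <- population[i + 1L, seg]
      population[i + 1L, seg] <- tmp
    }
  }
  population
}

#' Run one genetic-algorithm search
#'
#' Per generation: evaluate the fitness of every chromosome, apply elitist
#' selection (recording the generation-best solution), then mutation, then
#' crossover. Returns the full sequence of generation-best records; by the
#' elitist construction their fitness is non-decreasing.
#'
#' @param panel_mat Numeric matrix, panel genes x samples (log2 scale);
#'   rownames are the panel gene ids.
#' @param labels 0/1 label vector over the samples.
#' @param measure Fitness measure (`"acc"`, `"mcc"`, `"f1"`, `"hybrid"`).
#' @param ga_cfg A [ga_config()]; its `seed` drives this run.
#' @param svm_cfg An [svm_fitness_config()] (its `measure` field is
#'   overridden by `measure`).
#' @param fold_id Optional fixed fold assignment; defaults to stratified
#'   folds derived from the run seed.
#' @param cache Optional confusion cache from `new_fitness_cache()`,
#'   shared across runs with identical folds.
#' @return List of class `ga_run`: `omega_bits` (generations x L matrix),
#'   `omega_fitness` (length `generations`), `measure`, `fold_id`.
#' @export
run_ga <- function(panel_mat, labels, measure, ga_cfg, svm_cfg,
                   fold_id = NULL, cache = NULL) {
  measure <- match.arg(measure, MEASURES)
  labels <- assert_labels(labels)
  if (length(labels) != ncol(panel_mat)) {
    stopf("labels must match panel matrix columns")
  }
  if (!inherits(ga_cfg, "ga_config")) stopf("`ga_cfg` must be a ga_config")
  if (!inherits(svm_cfg, "svm_fitness_config")) {
    stopf("`svm_cfg` must be an svm_fitness_config")
  }
  n_bits <- nrow(panel_mat)
  seeds <- derive_seeds(ga_cfg$seed, 2L)
  if (is.null(fold_id)) fold_id <- make_folds(labels, svm_cfg$folds, seeds[1L])
  if (is.null(cache)) cache <- new_fitness_cache()
  delta <- sum(labels == 1L) / sum(labels == 0L)

  fitness_of <- function(bits) {
    if (sum(bits) == 0L) return(measure_floor(measure))
    counts <- cached_grid_confusions(bits, panel_mat, labels, fold_id,
                                     svm_cfg, cache)
    max(metric_from_counts(counts, measure, delta))
  }

  omega_bits <- matrix(0L, ga_cfg$generations, n_bits,
                       dimnames = list(NULL, rownames(panel_mat)))
  omega_fitness <- numeric(ga_cfg$generations)

  with_seed(seeds[2L], {
    population <- init_population(ga_cfg, n_bits)
    state <- NULL
    for (tau in seq_len(ga_cfg$generations)) {
      fitnesses <- apply(population, 1L, fitness_of)
      sel <- select_elites(population, fitnesses, state)
      state <- sel$state
      omega_bits[tau, ] <- sel$omega$bits
      omega_fitness[tau] <- sel$omega$fitness
      population <- mutate_population(sel$population, ga_cfg$mutation_threshold)
      population <- crossover_population(population, ga_cfg$crossover_threshold)
    }
  })
  structure(list(omega_bits = omega_bits, omega_fitness = omega_fitness,
                 measure = measure, fold_id = fold_id),
            class = "ga_run")
}

#' Run the full selection procedure
#'
#' For each fitness measure, the GA is repeated `repeats` times (each
#' repeat re-seeded from the master seed; repeat seeds are shared across
#' measures), accumulating `repeats x generations` generation-best records
#' per measure — 2,000 at the canonical settings. Records with identical
#' bit vectors are deduplicated (first occurrence kept; fitness is
#' identical by determinism) and the remainder ranked by fitness,
#' descending, of which the top `top_k` are retained for scoring. CV folds
#' are fixed once for the whole procedure so every fitness value is a pure
#' function of the bit vector, and the confusion cache is shared across
#' measures and repeats.
#'
#' @param panel_mat Numeric matrix, panel genes x samples; rownames are the
#'   panel gene ids.
#' @param labels 0/1 label vector over the samples.
#' @param ga_cfg A [ga_config()]; `seed` is the master seed.
#' @param svm_cfg An [svm_fitness_config()]; its `measure` field is ignored
#'   (all requested measures are run).
#' @param measures Fitness measures to run (default all four).
#' @param top_k Solutions retained per measure after deduplication.
#' @return An object of class `solution_archive`: per measure a list with
#'   `records` (all generation-best bits and fitness, pre-deduplication),
#'   `top` (deduplicated, ranked, truncated) and `shortfall` (TRUE when
#'   fewer than `top_k` unique solutions existed); plus `gene_ids`,
#'   `n_pos`/`n_neg` and the configs.
#' @export
run_selection_procedure <- function(panel_mat, labels, ga_cfg, svm_cfg,
                                    measures = MEASURES, top_k = 10L) {
  labels <- assert_labels(labels)
  if (!inherits(ga_cfg, "ga_config")) stopf("`ga_cfg` must be a ga_config")
  if (!inherits(svm_cfg, "svm_fitness_config")) {
    stopf("`svm_cfg` must be an svm_fitness_config")
  }
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  assert_count(top_k, "top_k", min = 1L)

  seeds <- derive_seeds(ga_cfg$seed, 1L + ga_cfg$repeats)
  fold_id <- make_folds(labels, svm_cfg$folds, seeds[1L])
  cache <- new_fitness_cache()

  per_measure <- lapply(measures, function(m) {
    runs <- lapply(seq_len(ga_cfg$repeats), function(r) {
      rep_cfg <- ga_cfg
      rep_cfg$seed <- seeds[1L + r]
      run_ga(panel_mat, labels, m, rep_cfg, svm_cfg,
             fold_id = fold_id, cache = cache)
    })
    bits <- do.call(rbind, lapply(runs, `[[`, "omega_bits"))
    fitness <- unlist(lapply(runs, `[[`, "omega_fitness"), use.names = FALSE)

    keys <- apply(bits, 1L, paste, collapse = "")
    keep <- !duplicated(keys)
    ubits <- bits[keep, , drop = FALSE]
    ufit <- fitness[keep]
    ord <- order(-ufit)  # stable: earlier record wins ties
    shortfall <- length(ufit) < top_k
    sel <- ord[seq_len(min(top_k, length(ord)))]
    list(records = list(bits = bits, fitness = fitness),
         top = list(bits = ubits[sel, , drop = FALSE], fitness = ufit[sel]),
         shortfall = shortfall)
  })
  names(per_measure) <- measures
  structure(list(measures = per_measure, gene_ids = rownames(panel_mat),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 top_k = as.integer(top_k), ga_cfg = ga_cfg,
                 svm_cfg = svm_cfg),
            class = "solution_archive")
}

#' @export
print.solution_archive <- function(x, ...) {
  cat(sprintf("<solution_archive> %d measure(s), %d-gene panel\n",
              length(x$measures), length(x$gene_ids)))
  for (m in names(x$measures)) {
    top <- x$measures[[m]]$top
    cat(sprintf("  %-6s: %d records, top-%d best fitness %.4f%s\n", m,
                nrow(x$measures[[m]]$records$bits), nrow(top$bits),
                top$fitness[1L],
                if (x$measures[[m]]$shortfall) " (shortfall)" else ""))
  }
  invisible(x)
}
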