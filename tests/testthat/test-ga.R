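test_that("initial populations are Bernoulli(0.5) with no empty chromosome", {
  cfg <- ga_config(seed = 1)
  set.seed(11)
  pop <- init_population(cfg, 100)
  expect_equal(dim(pop), c(80L, 100L))
  expect_true(all(rowSums(pop) > 0))
  # mean set-bit count within a 5-sigma binomial band around 50
  expect_lt(abs(mean(rowSums(pop)) - 50), 5 * 5 / sqrt(80))
})

test_that("configuration invariants are enforced", {
  expect_error(ga_config(population_size = 7), "even")
  expect_error(ga_config(population_size = 2), "population_size")
  expect_error(ga_config(mutation_threshold = 1.2), "mutation_threshold")
})

test_that("elitist selection keeps the best per half and copies them forward", {
  pop <- rbind(diag(1L, 4L), matrix(1L, 2, 4))  # 6 chromosomes, length 4
  fit <- c(0.2, 0.9, 0.1, 0.5, 0.3, 0.3)
  sel <- select_elites(pop, fit)
  expect_equal(sel$state$alpha$fitness, 0.9)
  expect_equal(sel$state$alpha$bits, pop[2, ])
  expect_equal(sel$state$beta$fitness, 0.5)   # best of rows 4:6
  expect_equal(sel$omega$fitness, 0.9)
  # odd rows copy alpha, even rows copy beta
  expect_true(all(apply(sel$population[c(1, 3, 5), ], 1,
                        identical, sel$state$alpha$bits)))
  expect_true(all(apply(sel$population[c(2, 4, 6), ], 1,
                        identical, sel$state$beta$bits)))

  # ties resolve to the lowest index
  tie <- select_elites(pop, rep(0.4, 6))
  expect_equal(tie$state$alpha$bits, pop[1, ])
  expect_equal(tie$state$beta$bits, pop[4, ])
})

test_that("previous elites persist until strictly beaten", {
  pop <- matrix(0L, 4, 3)
  pop[, 1] <- 1L
  first <- select_elites(pop, c(0.8, 0.1, 0.7, 0.2))
  worse <- matrix(1L, 4, 3)
  second <- select_elites(worse, c(0.5, 0.5, 0.6, 0.6), first$state)
  expect_equal(second$state$alpha$fitness, 0.8)   # kept from before
  expect_equal(second$state$alpha$bits, pop[1, ])
  expect_gte(second$omega$fitness, first$omega$fitness)
})

test_that("mutation applies the two schemes to the two halves", {
  pop <- matrix(0L, 20, 50)
  set.seed(5)
  none <- mutate_population(pop, mutation_threshold = 0)
  expect_equal(none[1:10, ], pop[1:10, ])          # first half untouched
  expect_true(all(rowSums(none[11:20, ] != 0L) == 1))  # exactly one flip

  set.seed(6)
  all_flip <- mutate_population(pop, mutation_threshold = 1)
  expect_true(all(all_flip[1:10, ] == 1L))         # full complement

  # expected flips per first-half chromosome = 0.1 * 50 = 5
  set.seed(7)
  flips <- replicate(200, {
    m <- mutate_population(matrix(0L, 2, 50), 0.1)
    sum(m[1, ])
  })
  expect_lt(abs(mean(flips) - 5), 5 * sqrt(5 * 0.9) / sqrt(200))
})

test_that("one-point crossover swaps suffixes and conserves pairs", {
  set.seed(9)
  pop <- matrix(sample(c(0L, 1L), 20 * 30, replace = TRUE), 20, 30)
  unchanged <- crossover_population(pop, crossover_threshold = 0)
  expect_identical(unchanged, pop)

  set.seed(10)
  crossed <- crossover_population(pop, crossover_threshold = 1)
  for (k in 1:10) {
    i <- 2L * k - 1L
    # per-position multiset within each pair is conserved
    expect_equal(crossed[i, ] + crossed[i + 1L, ], pop[i, ] + pop[i + 1L, ])
    # changed positions form a suffix swapped between the two chromosomes
    diffs <- which(crossed[i, ] != pop[i, ])
    if (length(diffs) > 0) {
      lambda <- min(diffs)
      expect_identical(crossed[i, lambda:30], pop[i + 1L, lambda:30])
      expect_identical(crossed[i + 1L, lambda:30], pop[i, lambda:30])
      expect_identical(crossed[i, seq_len(lambda - 1L)],
                       pop[i, seq_len(lambda - 1L)])
    }
  }
})

test_that("a GA run returns one monotone generation-best record per generation", {
  sim <- tiny_sim(seed = 3)
  pm <- sim$matrix$values[1:20, ]
  cfg <- quick_ga_cfg(seed = 21, generations = 6)
  run <- run_ga(pm, sim$labels, "mcc", cfg, quick_svm_cfg())
  expect_equal(nrow(run$omega_bits), 6L)
  expect_length(run$omega_fitness, 6L)
  expect_true(all(diff(run$omega_fitness) >= 0))
})

test_that("search improves over random initialization on informative data", {
  sim <- gen_two_class_expression(
    simulation_design(n_pos = 30, n_neg = 30, n_genes = 40, n_up = 3,
                      n_down = 3, effect_size = 1, noise_sd = 1, seed = 2))
  pm <- sim$matrix$values[1:20, ]
  improved <- vapply(1:10, function(s) {
    cfg <- ga_config(population_size = 16, generations = 8, repeats = 1,
                     seed = 100 + s)
    run <- run_ga(pm, sim$labels, "mcc", cfg, quick_svm_cfg())
    run$omega_fitness[8] >= run$omega_fitness[1] &&
      run$omega_fitness[8] > 0
  }, logical(1))
  expect_gte(sum(improved), 9)
})

test_that("the selection procedure accumulates, deduplicates and ranks", {
  sim <- tiny_sim(seed = 7)
  pm <- sim$matrix$values[1:20, ]
  cfg <- quick_ga_cfg(seed = 31, generations = 5, repeats = 3)
  arch <- run_selection_procedure(pm, sim$labels, cfg, quick_svm_cfg(),
                                  measures = c("mcc", "acc"), top_k = 4)
  for (m in c("mcc", "acc")) {
    rec <- arch$measures[[m]]
    expect_equal(nrow(rec$records$bits), 3L * 5L)  # repeats x generations
    keys <- apply(rec$top$bits, 1, paste, collapse = "")
    expect_equal(anyDuplicated(keys), 0L)
    expect_true(all(diff(rec$top$fitness) <= 0))
    expect_lte(nrow(rec$top$bits), 4L)
  }
  expect_identical(arch$gene_ids, rownames(pm))
})

test_that("one master seed reproduces the whole archive byte for byte", {
  sim <- tiny_sim(seed = 5)
  pm <- sim$matrix$values[1:15, ]
  cfg <- quick_ga_cfg(seed = 77, generations = 4, repeats = 2)
  a <- run_selection_procedure(pm, sim$labels, cfg, quick_svm_cfg(),
                               measures = c("mcc", "hybrid"))
  b <- run_selection_procedure(pm, sim$labels, cfg, quick_svm_cfg(),
                               measures = c("mcc", "hybrid"))
  expect_identical(a, b)
  fa <- tempfile(fileext = ".tsv")
  fb <- tempfile(fileext = ".tsv")
  write_archive_tsv(a, fa)
  write_archive_tsv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})
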