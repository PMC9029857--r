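# Shared fixture builders. Everything is generated in code at test time;
# small configurations keep individual tests fast while the end-to-end
# tests run the calibrated scales.

tiny_design <- function(seed = 3, effect_size = 2, n_pos = 25, n_neg = 25,
                        n_genes = 100, n_up = 5, n_down = 5) {
  simulation_design(n_pos = n_pos, n_neg = n_neg, n_genes = n_genes,
                    n_up = n_up, n_down = n_down, effect_size = effect_size,
                    noise_sd = 1, seed = seed)
}

tiny_sim <- function(...) gen_two_class_expression(tiny_design(...))

quick_ga_cfg <- function(seed = 42, generations = 8, repeats = 2,
                         population_size = 16) {
  ga_config(population_size = population_size, generations = generations,
            repeats = repeats, seed = seed)
}

quick_svm_cfg <- function(measure = "mcc", ...) {
  svm_fitness_config(measure, cost_exponents = c(0, 6),
                     gamma_exponents = c(-7, -3), ...)
}

# Hand-built solution archive for the scoring stage: `tops` is a named list
# (one element per measure) of 0/1 matrices, rows = ranked solutions.
make_archive <- function(tops, gene_ids, top_k = 10L) {
  measures <- lapply(tops, function(bits) {
    bits <- matrix(as.integer(bits), nrow = nrow(bits))
    list(records = list(bits = bits, fitness = rep(1, nrow(bits))),
         top = list(bits = bits, fitness = rep(1, nrow(bits))),
         shortfall = nrow(bits) < top_k)
  })
  structure(list(measures = measures, gene_ids = gene_ids,
                 n_pos = 1L, n_neg = 1L, top_k = as.integer(top_k),
                 ga_cfg = NULL, svm_cfg = NULL),
            class = "solution_archive")
}

# Independent running-sum oracle: a literal loop over the ranked list,
# recomputing member weights from scratch. Kept deliberately naive.
brute_force_ec <- function(gene_order, stats, members, weight_exponent) {
  in_set <- gene_order %in% members
  n <- length(gene_order)
  nh <- sum(in_set)
  wsum <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) wsum <- wsum + abs(stats[i])^weight_exponent
  }
  best <- -Inf
  run <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      run <- run + (if (wsum > 0) abs(stats[i])^weight_exponent / wsum else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (run > best) best <- run
  }
  best
}

# Confusion-table generator for metric oracle checks.
random_confusion <- function() {
  repeat {
    x <- sample(0:60, 4, replace = TRUE)
    if (sum(x) >= 1) {
      return(confusion_counts(tp = x[1], tn = x[2], fp = x[3], fn = x[4]))
    }
  }
}

# Binary truth/prediction vectors realizing a confusion table.
cc_vectors <- function(cc) {
  truth <- c(rep(1, cc$tp), rep(0, cc$tn), rep(0, cc$fp), rep(1, cc$fn))
  pred <- c(rep(1, cc$tp), rep(0, cc$tn), rep(1, cc$fp), rep(0, cc$fn))
  list(truth = truth, pred = pred)
}
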