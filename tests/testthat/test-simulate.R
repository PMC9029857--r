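test_that("design validation names the offending field", {
  expect_error(simulation_design(n_pos = -1), "n_pos")
  expect_error(simulation_design(noise_sd = 0), "noise_sd")
  expect_error(simulation_design(n_genes = 10, n_up = 8, n_down = 8), "n_up")
})

test_that("simulated matrix has the designed shape and labels", {
  d <- simulation_design(n_pos = 228, n_neg = 148, n_genes = 300,
                         n_up = 10, n_down = 10, seed = 1)
  sim <- gen_two_class_expression(d)
  expect_equal(dim(sim$matrix), c(300L, 376L))
  expect_equal(sum(sim$labels == 1L), 228)
  expect_equal(sum(sim$labels == 0L), 148)
  expect_equal(sim$matrix$scale, "log2")
  expect_length(sim$truth$planted_up, 10)
  expect_length(sim$truth$planted_down, 10)
  expect_length(intersect(sim$truth$planted_up, sim$truth$planted_down), 0)
})

test_that("identical seeds reproduce bit-identical data; distinct seeds differ", {
  a <- gen_two_class_expression(tiny_design(seed = 7))
  b <- gen_two_class_expression(tiny_design(seed = 7))
  c <- gen_two_class_expression(tiny_design(seed = 8))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("planted genes carry the designed effect and null designs do not", {
  d <- simulation_design(n_pos = 100, n_neg = 100, n_genes = 200,
                         n_up = 10, n_down = 10, effect_size = 2,
                         noise_sd = 1, seed = 5)
  sim <- gen_two_class_expression(d)
  diff <- rowMeans(sim$matrix$values[, sim$labels == 1L]) -
    rowMeans(sim$matrix$values[, sim$labels == 0L])
  se <- sqrt(2 / 100)  # sd of a difference of two 100-sample means at sd 1
  expect_true(all(abs(diff[sim$truth$planted_up] - 2) < 5 * se))
  expect_true(all(abs(diff[sim$truth$planted_down] + 2) < 5 * se))

  null <- gen_two_class_expression(
    simulation_design(n_pos = 100, n_neg = 100, n_genes = 200,
                      n_up = 0, n_down = 0, effect_size = 0, seed = 6))
  ndiff <- rowMeans(null$matrix$values[, null$labels == 1L]) -
    rowMeans(null$matrix$values[, null$labels == 0L])
  expect_true(all(abs(ndiff) < 3 * 1 / sqrt(100) * sqrt(2)))
})

test_that("linear output exponentiates the log2 matrix", {
  d <- tiny_design(seed = 2)
  log2_out <- gen_two_class_expression(d)
  lin_out <- gen_two_class_expression(d, output_scale = "linear")
  expect_equal(lin_out$matrix$scale, "linear")
  expect_equal(lin_out$matrix$values, 2^log2_out$matrix$values)
})

test_that("gene sets respect size bounds and enrichment guarantees", {
  sim <- tiny_sim(n_genes = 200, n_up = 15, n_down = 15)
  sets <- gen_gene_sets(rownames(sim$matrix$values), sim$truth,
                        n_sets = 20, size_min = 15, size_max = 50,
                        enriched_fraction = 0.5, seed = 3)
  expect_length(sets, 20)
  sizes <- lengths(sets)
  expect_true(all(sizes >= 15 & sizes <= 50))
  expect_true(all(vapply(sets, anyDuplicated, integer(1)) == 0L))

  planted <- c(sim$truth$planted_up, sim$truth$planted_down)
  enriched <- attr(sets, "enriched")
  share <- vapply(sets, function(s) sum(s %in% planted), integer(1))
  # every enriched set draws at least ceiling(half its size) planted members,
  # capped by the 30 planted genes available
  need <- pmin(ceiling(sizes / 2), length(planted))
  expect_true(all(share[enriched] >= need[enriched]))
})

test_that("unenriched collections sample planted genes at the uniform rate", {
  sim <- tiny_sim(n_genes = 500, n_up = 25, n_down = 25)
  sets <- gen_gene_sets(rownames(sim$matrix$values), sim$truth,
                        n_sets = 40, size_min = 20, size_max = 40,
                        enriched_fraction = 0, seed = 9)
  planted <- c(sim$truth$planted_up, sim$truth$planted_down)
  hits <- sum(vapply(sets, function(s) sum(s %in% planted), integer(1)))
  total <- sum(lengths(sets))
  p <- length(planted) / 500
  expect_gt(binom.test(hits, total, p)$p.value, 0.01)
})

test_that("gene-set generation rejects impossible requests", {
  expect_error(gen_gene_sets(character(), list(), n_sets = 2), "empty")
  expect_error(
    gen_gene_sets(letters, list(planted_up = "a", planted_down = character()),
                  n_sets = 2, size_min = 10, size_max = 40),
    "size_min")
})

test_that("fixture bundles round-trip losslessly", {
  sim <- tiny_sim(seed = 11)
  sets <- gen_gene_sets(rownames(sim$matrix$values), sim$truth,
                        n_sets = 5, size_min = 5, size_max = 10, seed = 2)
  out <- withr::local_tempdir()
  paths <- write_fixture_bundle(sim$matrix, sim$labels, sets, out)
  expect_true(all(file.exists(paths)))

  back <- read_expression_tsv(paths[["expression"]], scale = "log2")
  expect_equal(back$values, sim$matrix$values)
  expect_identical(read_labels_csv(paths[["labels"]]), sim$labels)
  rt_sets <- read_gmt(paths[["gene_sets"]])
  expect_identical(names(rt_sets), names(sets))
  expect_true(all(mapply(identical, rt_sets, sets)))

  # GMT line format: name <TAB> description <TAB> members...
  line1 <- strsplit(readLines(paths[["gene_sets"]])[1], "\t")[[1]]
  expect_identical(line1[1], names(sets)[1])
  expect_identical(line1[-(1:2)], sets[[1]])
})

test_that("degenerate matrices cannot be constructed or written", {
  expect_error(expr_matrix(matrix(numeric(0), 0, 0), "log2"), "at least one")
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  storage.mode(m) <- "double"
  expect_error(
    write_fixture_bundle(expr_matrix(m, "log2"), c(s1 = 1L, s2 = 0L),
                         NULL, file.path(tempfile(), "x", "y", "z")),
    NA)  # nested dirs are created; only truly unwritable paths fail
})

test_that("planted effects are recoverable by the screening statistic", {
  sim <- gen_two_class_expression(
    simulation_design(n_pos = 50, n_neg = 50, n_genes = 500, n_up = 10,
                      n_down = 10, effect_size = 2, noise_sd = 1, seed = 21))
  snr <- signal_to_noise(sim$matrix, sim$labels)
  null_genes <- setdiff(names(snr), c(sim$truth$planted_up,
                                      sim$truth$planted_down))
  expect_gt(mean(snr[sim$truth$planted_up]),
            quantile(snr[null_genes], 0.95))
  expect_lt(mean(snr[sim$truth$planted_down]),
            quantile(snr[null_genes], 0.05))
})
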