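panel_of <- function(gene_ids, n_over = length(gene_ids) %/% 2) {
  structure(data.frame(
    gene_id = gene_ids,
    direction = rep(c("over", "under"),
                    c(n_over, length(gene_ids) - n_over)),
    statistic = seq(2, -2, length.out = length(gene_ids)),
    stringsAsFactors = FALSE),
    class = c("candidate_panel", "data.frame"))
}

test_that("selective scores hit the analytic landmarks", {
  genes <- sprintf("g%02d", 1:6)
  full <- matrix(0L, 10, 6)
  full[, 1] <- 1L                # gene 1 in every ranked solution
  full[6:10, 2] <- 1L            # gene 2 only at ranks 6-10
  full[1, 3] <- 1L               # gene 3 only in the top solution
  arch <- make_archive(list(acc = full, mcc = full, f1 = full, hybrid = full),
                       genes)
  sc <- selective_scores(arch)
  expect_equal(sc$score[1], 3)       # everywhere: (1 + 1 + 1) averaged over 4
  expect_equal(sc$score[4], 0)       # absent everywhere

  # ranks 6-10 of a single measure: (1/4) * (5/10 + 0 + 0)
  arch1 <- make_archive(list(acc = full,
                             mcc = matrix(0L, 10, 6),
                             f1 = matrix(0L, 10, 6),
                             hybrid = matrix(0L, 10, 6)), genes)
  sc1 <- selective_scores(arch1)
  expect_equal(sc1$score[2], 0.125)
  # top-rank presence counts three times: (1/10 + 1/5 + 1) / 4
  expect_equal(sc1$score[3], (1 / 10 + 1 / 5 + 1) / 4)
})

test_that("scores are monotone in every solution bit", {
  set.seed(55)
  genes <- sprintf("g%02d", 1:8)
  for (i in 1:20) {
    tops <- lapply(setNames(nm = c("acc", "mcc", "f1", "hybrid")), function(m)
      matrix(rbinom(80, 1, 0.4), 10, 8))
    base <- selective_scores(make_archive(tops, genes))$score
    zero <- which(tops$mcc == 0L)
    if (length(zero) == 0) next
    flip <- sample(zero, 1)
    tops$mcc[flip] <- 1L
    bumped <- selective_scores(make_archive(tops, genes))$score
    expect_true(all(bumped >= base - 1e-12))
  }
})

test_that("score 3 is attained exactly by omnipresent genes", {
  genes <- sprintf("g%02d", 1:4)
  tops <- lapply(setNames(nm = c("acc", "mcc", "f1", "hybrid")), function(m) {
    b <- matrix(0L, 10, 4)
    b[, 1] <- 1L
    b[1:9, 2] <- 1L  # misses one counted solution
    b
  })
  sc <- selective_scores(make_archive(tops, genes))
  expect_equal(sc$score[1], 3)
  expect_lt(sc$score[2], 3)
})

test_that("shortfall archives score missing ranks as zero", {
  genes <- c("a", "b")
  short <- matrix(1L, 3, 2)  # only 3 unique solutions survived dedup
  arch <- make_archive(list(acc = short, mcc = short, f1 = short,
                            hybrid = short), genes)
  # per measure (3/10 + 3/5 + 1); the four identical measures average to it
  expect_equal(selective_scores(arch)$score[1], 3 / 10 + 3 / 5 + 1)
})

test_that("signature extraction filters, sorts and attaches directions", {
  genes <- c("A", "B", "C")
  panel <- panel_of(genes, n_over = 1)
  sc <- structure(data.frame(gene_id = genes, score = c(2.5, 1.9, 2.0),
                             stringsAsFactors = FALSE),
                  class = c("selective_score_table", "data.frame"))
  sig <- extract_signature(sc, panel, threshold = 2)
  expect_identical(sig$gene_id, c("A", "C"))
  expect_identical(sig$direction, c("over", "under"))

  all_in <- extract_signature(sc, panel, threshold = 0)
  expect_equal(nrow(all_in), 3)
  top_only <- extract_signature(sc, panel, threshold = 2.5)
  expect_identical(top_only$gene_id, "A")
  # signature size is non-increasing in the threshold
  sizes <- vapply(seq(0, 3, by = 0.5), function(th)
    nrow(extract_signature(sc, panel, th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("combining runs reproduces union/intersection bookkeeping", {
  mk_sig <- function(ids, dirs, scores = rep(2.5, length(ids))) {
    structure(data.frame(gene_id = ids, score = scores, direction = dirs,
                         stringsAsFactors = FALSE),
              class = c("signature_genes", "data.frame"))
  }
  a_ids <- sprintf("A%02d", 1:19)
  b_ids <- c(sprintf("B%02d", 1:14), a_ids[1:3])  # 17 genes, 3 shared
  sig_a <- mk_sig(a_ids, rep(c("over", "under"), c(6, 13)))
  sig_b <- mk_sig(b_ids, c(rep(c("over", "under"), c(7, 7)),
                           rep(c("over", "under"), c(6, 13))[1:3]))
  comb <- combine_signatures(sig_a, sig_b, c("GBM1", "GBM2"))
  expect_equal(nrow(comb$genes), 19 + 17 - 3)
  expect_length(comb$intersection, 3)
  expect_false(any(comb$genes$conflict))
  expect_equal(unname(comb$counts["GBM1", ]), c(6, 13))

  disjoint <- combine_signatures(mk_sig(sprintf("X%02d", 1:19),
                                        rep("over", 19)),
                                 mk_sig(sprintf("Y%02d", 1:17),
                                        rep("under", 17)))
  expect_equal(nrow(disjoint$genes), 36)
  expect_length(disjoint$intersection, 0)

  same <- combine_signatures(sig_a, sig_a, c("r1", "r2"))
  expect_equal(nrow(same$genes), 19)
  expect_length(same$intersection, 19)

  conflicted <- combine_signatures(mk_sig("G1", "over"), mk_sig("G1", "under"))
  expect_true(conflicted$genes$conflict[1])
  expect_identical(conflicted$genes$direction[1], "conflict")
})

test_that("heatmap export z-scales rows and groups columns by class", {
  sim <- tiny_sim(seed = 19, effect_size = 2)
  genes <- c(sim$truth$planted_up[1:3], sim$truth$planted_down[1:3])
  sig <- structure(data.frame(gene_id = genes, score = rep(3, 6),
                              direction = rep(c("over", "under"), each = 3),
                              stringsAsFactors = FALSE),
                   class = c("signature_genes", "data.frame"))
  hm <- heatmap_matrix(sim$matrix, sig, sim$labels)
  expect_equal(dim(hm), c(6L, 50L))
  expect_equal(unname(rowMeans(hm)), rep(0, 6))
  expect_equal(unname(apply(hm, 1, sd)), rep(1, 6))
  expect_identical(attr(hm, "direction"), rep(c("over", "under"), each = 3))
  cls <- attr(hm, "phenotype")
  expect_identical(cls, c(rep(1L, 25), rep(0L, 25)))
  # planted-up rows are higher in the positive-class block
  up_rows <- hm[1:3, , drop = FALSE]
  expect_true(all(rowMeans(up_rows[, cls == 1L]) >
                    rowMeans(up_rows[, cls == 0L])))

  one <- heatmap_matrix(sim$matrix, sig[1, ], sim$labels)
  expect_equal(nrow(one), 1L)
  bad <- sig
  bad$gene_id[1] <- "NOPE"
  expect_error(heatmap_matrix(sim$matrix, bad, sim$labels), "NOPE")
})
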