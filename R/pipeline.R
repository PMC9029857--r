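#' End-to-end signature discovery
#'
#' Convenience wrapper chaining the pipeline on an already log2-scaled
#' matrix: signal-to-noise ranking, candidate screening (optionally
#' restricted to positively enriched gene sets), the repeated GA/SVM
#' selection procedure over the four fitness measures, selective scoring
#' and signature extraction.
#'
#' @param matrix An [expr_matrix()] on the log2 scale.
#' @param labels 0/1 label vector over the samples.
#' @param gene_sets Optional named gene-set list for the screening
#'   restriction.
#' @param n_per_tail Candidates per tail (default 50).
#' @param ga_cfg A [ga_config()].
#' @param svm_cfg An [svm_fitness_config()].
#' @param threshold Selective-score threshold for the signature (default 2).
#' @param measures Fitness measures to run (default all four).
#' @return A list with `ranked`, `panel`, `archive`, `scores` and
#'   `signature`.
#' @examples
#' \donttest{
#' sim <- gen_two_class_expression(
#'   simulation_design(n_pos = 30, n_neg = 30, n_genes = 60,
#'                     n_up = 5, n_down = 5, seed = 1))
#' res <- discover_signature(
#'   sim$matrix, sim$labels, n_per_tail = 5,
#'   ga_cfg = ga_config(population_size = 20, generations = 5,
#'                      repeats = 2, seed = 1),
#'   svm_cfg = svm_fitness_config(grid_step = 10))
#' res$signature
#' }
#' @export
discover_signature <- function(matrix, labels, gene_sets = NULL,
                               n_per_tail = 50,
                               ga_cfg = ga_config(),
                               svm_cfg = svm_fitness_config(),
                               threshold = 2, measures = MEASURES) {
  assert_expr_matrix(matrix, scale = "log2")
  labels <- assert_labels(labels, matrix)
  ranked <- rank_genes(signal_to_noise(matrix, labels))
  panel <- screen_candidates(ranked, gene_sets, n_per_tail = n_per_tail)
  pm <- panel_matrix(matrix, panel)
  archive <- run_selection_procedure(pm, labels, ga_cfg, svm_cfg,
                                     measures = measures)
  scores <- selective_scores(archive)
  signature <- extract_signature(scores, panel, threshold)
  list(ranked = ranked, panel = panel, archive = archive,
       scores = scores, signature = signature)
}
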