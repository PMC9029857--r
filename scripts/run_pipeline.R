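#!/usr/bin/env Rscript
# End-to-end run from files on disk: expression TSV + labels CSV (+ optional
# GMT), through normalization (if the matrix is on the linear scale),
# screening, GA/SVM selection and signature extraction. Thin wrapper over
# the package functions; see the package documentation for the full API.
#
# Usage:
#   Rscript scripts/run_pipeline.R --expression expr.tsv --labels labels.csv \
#     [--gene-sets sets.gmt] [--scale log2|linear] [--n-per-tail 50] \
#     [--threshold 2] [--fast] [--seed 1] --out results/

suppressPackageStartupMessages({
  library(optparse)
  library(sigevolve)
})

opt_list <- list(
  make_option("--expression", type = "character"),
  make_option("--labels", type = "character"),
  make_option("--gene-sets", type = "character", default = NULL,
              dest = "gene_sets"),
  make_option("--scale", type = "character", default = "log2"),
  make_option("--n-per-tail", type = "integer", default = 50L,
              dest = "n_per_tail"),
  make_option("--threshold", type = "double", default = 2),
  make_option("--fast", action = "store_true", default = FALSE,
              help = "8x8 hyperparameter grid and a scaled GA (20 generations, 3 repeats)"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results")
)
opts <- parse_args(OptionParser(option_list = opt_list))
if (is.null(opts$expression) || is.null(opts$labels)) {
  stop("--expression and --labels are required", call. = FALSE)
}

em <- read_expression_tsv(opts$expression, scale = opts$scale)
if (em$scale == "linear") {
  em <- log2_transform(linear_scale(em))
}
labels <- read_labels_csv(opts$labels)
sets <- if (!is.null(opts$gene_sets)) read_gmt(opts$gene_sets) else NULL

ga_cfg <- if (opts$fast) {
  ga_config(generations = 20, repeats = 3, seed = opts$seed)
} else {
  ga_config(seed = opts$seed)
}
svm_cfg <- svm_fitness_config(grid_step = if (opts$fast) 4 else 1)

res <- discover_signature(em, labels, gene_sets = sets,
                          n_per_tail = opts$n_per_tail,
                          ga_cfg = ga_cfg, svm_cfg = svm_cfg,
                          threshold = opts$threshold)

if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
write_panel_tsv(res$panel, file.path(opts$out, "panel.tsv"))
write_archive_tsv(res$archive, file.path(opts$out, "archive.tsv"))
write.table(as.data.frame(res$scores), file.path(opts$out, "scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(res$signature),
            file.path(opts$out, "signature.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(res$signature) > 0) {
  hm <- heatmap_matrix(em, res$signature, labels)
  write.table(data.frame(gene_id = rownames(hm), hm, check.names = FALSE),
              file.path(opts$out, "heatmap_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(
  list(seed = opts$seed, fast = opts$fast, n_per_tail = opts$n_per_tail,
       threshold = opts$threshold, n_signature = nrow(res$signature)),
  file.path(opts$out, "manifest.json"), auto_unbox = TRUE)
cat(sprintf("signature: %d gene(s) -> %s\n", nrow(res$signature), opts$out))
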