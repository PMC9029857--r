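#' Design of a two-class synthetic expression experiment
#'
#' Describes the simulated cohort: class sizes, gene universe, how many genes
#' are planted as over- or underexpressed in the positive class, the planted
#' effect size and the per-gene noise level, all in log2 units. Defaults
#' mirror a two-cohort microarray comparison of 228 positive (tumor of
#' interest) versus 148 negative samples.
#'
#' @param n_pos,n_neg Positive- and negative-class sample counts.
#' @param n_genes Total number of genes in the simulated universe.
#' @param n_up Genes overexpressed in the positive class.
#' @param n_down Genes underexpressed in the positive class.
#' @param effect_size Planted mean shift in log2 units (a value of 2 is a
#'   four-fold intensity change, typical of strongly differential microarray
#'   genes).
#' @param noise_sd Per-gene Gaussian standard deviation in log2 units
#'   (log-intensity residual spread of ~1 is typical for single-channel
#'   arrays).
#' @param baseline_mean Baseline log2 intensity shared by all genes.
#' @param seed RNG seed; identical seeds give bit-identical simulations.
#' @return An object of class `simulation_design`.
#' @examples
#' design <- simulation_design(n_pos = 50, n_neg = 50, n_genes = 200,
#'                             n_up = 5, n_down = 5, seed = 1)
#' @export
simulation_design <- function(n_pos = 228, n_neg = 148, n_genes = 1000,
                              n_up = 50, n_down = 50, effect_size = 2,
                              noise_sd = 1, baseline_mean = 8, seed = 1) {
  assert_count(n_pos, "n_pos", min = 1L)
  assert_count(n_neg, "n_neg", min = 1L)
  assert_count(n_genes, "n_genes", min = 1L)
  assert_count(n_up, "n_up")
  assert_count(n_down, "n_down")
  if (n_up + n_down > n_genes) {
    stopf("`n_up` + `n_down` (%d) exceeds `n_genes` (%d)",
          n_up + n_down, n_genes)
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1L || is.na(effect_size)) {
    stopf("`effect_size` must be a single number")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd <= 0) {
    stopf("`noise_sd` must be a single positive number")
  }
  if (!is.numeric(baseline_mean) || length(baseline_mean) != 1L ||
      is.na(baseline_mean)) {
    stopf("`baseline_mean` must be a single number")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_genes = as.integer(n_genes), n_up = as.integer(n_up),
                 n_down = as.integer(n_down), effect_size = effect_size,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a two-class expression matrix with planted differential genes
#'
#' Gene-level model: every value is `baseline + class shift + N(0, noise_sd)`
#' in log2 space. Planted overexpressed genes have positive-class mean
#' `baseline + effect_size`; planted underexpressed genes have
#' `baseline - effect_size`; all other genes share the baseline in both
#' classes. Noise is independent Gaussian per gene and sample (no
#' probe-level or batch structure).
#'
#' @param design A [simulation_design()].
#' @param output_scale `"log2"` (default) or `"linear"`; linear output
#'   exponentiates (`2^x`) so the preprocessing stage can be exercised.
#' @return A list with elements `matrix` (an [expr_matrix()]), `labels`
#'   (named 0/1 vector, 1 = positive class) and `truth` (list with
#'   `planted_up` and `planted_down` gene-id character vectors).
#' @examples
#' sim <- gen_two_class_expression(
#'   simulation_design(n_pos = 10, n_neg = 10, n_genes = 50,
#'                     n_up = 3, n_down = 3, seed = 42))
#' dim(sim$matrix)
#' table(sim$labels)
#' @export
gen_two_class_expression <- function(design, output_scale = c("log2", "linear")) {
  if (!inherits(design, "simulation_design")) {
    stopf("`design` must be a simulation_design object")
  }
  output_scale <- match.arg(output_scale)
  n <- design$n_pos + design$n_neg
  gid <- sprintf("G%06d", seq_len(design$n_genes))
  sid <- sprintf("S%04d", seq_len(n))
  labels <- c(rep(1L, design$n_pos), rep(0L, design$n_neg))
  names(labels) <- sid

  vals <- with_seed(design$seed, {
    planted_up <- if (design$n_up > 0) gid[seq_len(design$n_up)] else character()
    planted_down <- if (design$n_down > 0) {
      gid[design$n_up + seq_len(design$n_down)]
    } else {
      character()
    }
    mu <- matrix(design$baseline_mean, design$n_genes, n)
    if (design$n_up > 0) {
      mu[seq_len(design$n_up), labels == 1L] <-
        design$baseline_mean + design$effect_size
    }
    if (design$n_down > 0) {
      mu[design$n_up + seq_len(design$n_down), labels == 1L] <-
        design$baseline_mean - design$effect_size
    }
    mu + matrix(rnorm(design$n_genes * n, sd = design$noise_sd),
                design$n_genes, n)
  })
  dimnames(vals) <- list(gid, sid)

  planted_up <- if (design$n_up > 0) gid[seq_len(design$n_up)] else character()
  planted_down <- if (design$n_down > 0) {
    gid[design$n_up + seq_len(design$n_down)]
  } else {
    character()
  }
  em <- if (output_scale == "linear") {
    expr_matrix(2^vals, scale = "linear")
  } else {
    expr_matrix(vals, scale = "log2")
  }
  list(matrix = em, labels = labels,
       truth = list(planted_up = planted_up, planted_down = planted_down))
}

#' Simulate a gene-set collection with sets enriched for planted genes
#'
#' Builds a named collection of gene sets over the simulated gene universe,
#' in the spirit of a pathway-database collection. A fraction of the sets is
#' "enriched": at least half of each such set (capped by the number of
#' planted genes available) is drawn from the planted differential genes,
#' with the remainder drawn uniformly from the rest of the universe. The
#' remaining sets are drawn uniformly from the whole universe. No set
#' contains duplicate members.
#'
#' @param gene_ids Character vector, the gene universe.
#' @param truth Ground-truth list with `planted_up` / `planted_down`
#'   (as returned by [gen_two_class_expression()]); may have empty elements.
#' @param n_sets Number of sets to generate.
#' @param size_min,size_max Inclusive bounds on set sizes
#'   (`size_min <= size_max <= length(gene_ids)`).
#' @param enriched_fraction Fraction of sets enriched for planted genes.
#' @param seed RNG seed.
#' @return Named list of character vectors (class `gene_set_collection`),
#'   with a logical `enriched` attribute flagging the enriched sets.
#' @export
gen_gene_sets <- function(gene_ids, truth, n_sets = 50, size_min = 15,
                          size_max = 50, enriched_fraction = 0.3, seed = 1) {
  if (length(gene_ids) == 0L) stopf("the gene universe is empty")
  if (anyDuplicated(gene_ids)) stopf("`gene_ids` must be unique")
  assert_count(n_sets, "n_sets", min = 1L)
  assert_count(size_min, "size_min", min = 1L)
  assert_count(size_max, "size_max", min = 1L)
  if (size_min > size_max || size_max > length(gene_ids)) {
    stopf("need size_min <= size_max <= length(gene_ids)")
  }
  if (!is.numeric(enriched_fraction) || enriched_fraction < 0 ||
      enriched_fraction > 1) {
    stopf("`enriched_fraction` must be in [0, 1]")
  }
  planted <- unique(c(truth$planted_up, truth$planted_down))
  if (!all(planted %in% gene_ids)) {
    stopf("planted genes must belong to the gene universe")
  }
  other <- setdiff(gene_ids, planted)
  n_enriched <- round(n_sets * enriched_fraction)

  sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      size <- if (size_min == size_max) size_min else
        sample(seq.int(size_min, size_max), 1L)
      if (i <= n_enriched && length(planted) > 0) {
        k <- min(ceiling(size / 2), length(planted), size)
        core <- sample(planted, k)
        pool <- setdiff(gene_ids, core)
        rest <- if (size - k > 0) sample(pool, size - k) else character()
        sort(c(core, rest))
      } else {
        sort(sample(gene_ids, size))
      }
    })
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  structure(sets, class = c("gene_set_collection", "list"),
            enriched = seq_len(n_sets) <= n_enriched)
}

#' Write a simulated dataset as a fixture bundle
#'
#' Writes the expression matrix (TSV, first column `gene_id`), labels
#' (`sample_id,label` CSV), the gene sets (GMT) and a small JSON manifest
#' recording the scale tag. Files round-trip losslessly through
#' [read_expression_tsv()], [read_labels_csv()] and [read_gmt()].
#'
#' @param matrix An [expr_matrix()].
#' @param labels Named 0/1 label vector aligned with the matrix columns.
#' @param sets Named list of gene sets (may be `NULL` to skip the GMT).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixture_bundle <- function(matrix, labels, sets, out_dir) {
  assert_expr_matrix(matrix)
  labels <- assert_labels(labels, matrix)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             labels = file.path(out_dir, "labels.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_expression_tsv(matrix, paths[["expression"]])
  write_labels_csv(labels, paths[["labels"]])
  if (!is.null(sets)) {
    paths <- c(paths, gene_sets = file.path(out_dir, "gene_sets.gmt"))
    write_gmt(sets, paths[["gene_sets"]])
  }
  jsonlite::write_json(
    list(scale = matrix$scale, n_genes = nrow(matrix$values),
         n_samples = ncol(matrix$values)),
    paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
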