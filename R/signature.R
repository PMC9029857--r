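#' Per-gene selective scores from a solution archive
#'
#' Aggregates how often each panel gene is switched on across the
#' top-ranked solutions of the four fitness measures. With `f[j, q]` the
#' gene-j bit of the q-th ranked solution under measure p, the score is
#'
#' `r_j = (1/4) * sum_p [ (1/10) sum_{q=1..10} f + (1/5) sum_{q=1..5} f + f(q=1) ]`
#'
#' so a gene scores between 0 and 3 and reaches 3 only when it is present
#' in every counted solution of every measure; presence near the top of a
#' ranking counts up to three times. Archives with fewer than 10 unique
#' ranked solutions contribute 0 for the missing ranks (the divisors stay
#' 10, 5 and 1), which is conservative and keeps the score monotone in
#' every bit. The leading factor is `1/#measures`, which is 1/4 for the
#' canonical four-measure archive.
#'
#' @param archive A [run_selection_procedure()] archive.
#' @return A `selective_score_table` data.frame with columns `gene_id`,
#'   `score` and one per-measure component column, in panel order.
#' @export
selective_scores <- function(archive) {
  if (!inherits(archive, "solution_archive")) {
    stopf("`archive` must be a solution_archive")
  }
  if (length(archive$measures) == 0L) stopf("the archive is empty")
  gene_ids <- archive$gene_ids
  l <- length(gene_ids)
  top_k <- archive$top_k

  comp <- vapply(archive$measures, function(m) {
    bits <- m$top$bits
    n_ranked <- nrow(bits)
    counted <- function(k) {
      rows <- seq_len(min(k, n_ranked))
      colSums(bits[rows, , drop = FALSE]) / k
    }
    counted(top_k) + counted(max(1L, top_k %/% 2L)) + counted(1L)
  }, numeric(l))
  comp <- matrix(comp, nrow = l,
                 dimnames = list(NULL, names(archive$measures)))
  score <- rowMeans(comp)

  out <- data.frame(gene_id = gene_ids, score = score,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(comp))
  rownames(out) <- NULL
  structure(out, class = c("selective_score_table", "data.frame"))
}

#' Extract the signature of high-scoring genes
#'
#' Keeps the panel genes whose selective score is at or above the
#' threshold (default 2, i.e. genes selected in most top solutions of most
#' measures), sorted by score descending then gene id, with the over/under
#' direction carried over from the screening panel.
#'
#' @param scores A [selective_scores()] table.
#' @param panel The [screen_candidates()] panel the archive was built on.
#' @param threshold Minimum score, in \[0, 3\].
#' @return A `signature_genes` data.frame with columns `gene_id`, `score`
#'   and `direction`. May have zero rows.
#' @export
extract_signature <- function(scores, panel, threshold = 2) {
  if (!inherits(scores, "selective_score_table")) {
    stopf("`scores` must come from selective_scores()")
  }
  if (!inherits(panel, "candidate_panel")) {
    stopf("`panel` must be a candidate_panel")
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 3) {
    stopf("`threshold` must be in [0, 3]")
  }
  if (!all(scores$gene_id %in% panel$gene_id)) {
    stopf("score table contains genes absent from the panel")
  }
  keep <- scores[scores$score >= threshold, c("gene_id", "score")]
  keep$direction <- panel$direction[match(keep$gene_id, panel$gene_id)]
  keep <- keep[order(-keep$score, keep$gene_id), ]
  rownames(keep) <- NULL
  structure(keep, class = c("signature_genes", "data.frame"))
}

#' Combine the signatures of two runs
#'
#' Produces the union of two signature lists with per-gene membership
#' flags, the intersection, and per-run over/under counts — the dual-cohort
#' view in which a gene can be supported by either or both runs. A gene
#' assigned opposite directions by the two runs is flagged as a conflict,
#' not dropped.
#'
#' @param sig_a,sig_b [extract_signature()] results.
#' @param run_names Length-2 character vector naming the runs.
#' @return An object of class `combined_signature`: a list with `genes`
#'   (union data.frame: `gene_id`, `direction`, per-run scores and flags,
#'   `datasets`, `conflict`), `intersection` (gene ids in both),
#'   `counts` (over/under per run) and `run_names`.
#' @export
combine_signatures <- function(sig_a, sig_b, run_names = c("run1", "run2")) {
  for (s in list(sig_a, sig_b)) {
    if (!inherits(s, "signature_genes")) {
      stopf("both signatures must come from extract_signature()")
    }
  }
  if (length(run_names) != 2L || anyDuplicated(run_names)) {
    stopf("`run_names` must be two distinct names")
  }
  ids <- union(sig_a$gene_id, sig_b$gene_id)
  ia <- match(ids, sig_a$gene_id)
  ib <- match(ids, sig_b$gene_id)
  in_a <- !is.na(ia)
  in_b <- !is.na(ib)
  dir_a <- ifelse(in_a, sig_a$direction[ia], NA_character_)
  dir_b <- ifelse(in_b, sig_b$direction[ib], NA_character_)
  conflict <- in_a & in_b & dir_a != dir_b
  direction <- ifelse(in_a, dir_a, dir_b)
  direction[conflict] <- "conflict"
  genes <- data.frame(
    gene_id = ids, direction = direction,
    score_a = ifelse(in_a, sig_a$score[ia], NA_real_),
    score_b = ifelse(in_b, sig_b$score[ib], NA_real_),
    in_a = in_a, in_b = in_b,
    datasets = ifelse(in_a & in_b, paste(run_names, collapse = "+"),
                      ifelse(in_a, run_names[1L], run_names[2L])),
    conflict = conflict, stringsAsFactors = FALSE)
  genes <- genes[order(-(genes$in_a & genes$in_b),
                       -pmax(genes$score_a, genes$score_b, na.rm = TRUE),
                       genes$gene_id), ]
  rownames(genes) <- NULL
  counts <- rbind(
    table(factor(sig_a$direction, levels = c("over", "under"))),
    table(factor(sig_b$direction, levels = c("over", "under"))))
  rownames(counts) <- run_names
  structure(list(genes = genes,
                 intersection = intersect(sig_a$gene_id, sig_b$gene_id),
                 counts = counts, run_names = run_names),
            class = "combined_signature")
}

#' @export
print.combined_signature <- function(x, ...) {
  cat(sprintf("<combined_signature> union %d genes, intersection %d (%s)\n",
              nrow(x$genes), length(x$intersection),
              paste(x$run_names, collapse = " & ")))
  if (any(x$genes$conflict)) {
    cat(sprintf("  direction conflicts: %s\n",
                paste(x$genes$gene_id[x$genes$conflict], collapse = ", ")))
  }
  print(x$counts)
  invisible(x)
}

#' Heatmap-ready submatrix for a signature
#'
#' Selects the signature genes (overexpressed block first, then
#' underexpressed), groups columns by class (positive class first) and
#' z-scales each gene row to mean 0, sd 1 (rows with zero spread become
#' all-zero rather than NaN).
#'
#' @param matrix An [expr_matrix()] containing all signature genes.
#' @param signature An [extract_signature()] result with at least one gene.
#' @param labels 0/1 label vector over the matrix samples.
#' @return Numeric matrix (signature genes x reordered samples) with
#'   attributes `direction` (per row) and `phenotype` (0/1 per column).
#' @export
heatmap_matrix <- function(matrix, signature, labels) {
  assert_expr_matrix(matrix)
  if (!inherits(signature, "signature_genes") || nrow(signature) == 0L) {
    stopf("`signature` must be a non-empty signature_genes table")
  }
  labels <- assert_labels(labels, matrix)
  missing <- setdiff(signature$gene_id, gene_ids(matrix))
  if (length(missing) > 0L) {
    stopf("signature gene(s) absent from the matrix: %s",
          paste(missing, collapse = ", "))
  }
  sig <- signature[order(match(signature$direction, c("over", "under")),
                         -signature$score, signature$gene_id), ]
  col_order <- c(which(labels == 1L), which(labels == 0L))
  sub <- matrix$values[sig$gene_id, col_order, drop = FALSE]
  mu <- rowMeans(sub)
  s <- apply(sub, 1L, sd)
  s[s == 0] <- 1
  z <- sweep(sweep(sub, 1L, mu, `-`), 1L, s, `/`)
  attr(z, "direction") <- sig$direction
  attr(z, "phenotype") <- unname(labels[col_order])
  z
}
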