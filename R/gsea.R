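#' Signal-to-noise statistic per gene
#'
#' For each gene computes `(mu_pos - mu_neg) / (sd_pos + sd_neg)` on log2
#' data, the two-class difference statistic used to rank genes before
#' enrichment analysis. A positive value means overexpression in the
#' positive class. Each class standard deviation is floored at
#' `0.2 * |class mean|` (and at 0.2 when that is still zero), the
#' conventional guard against near-constant genes blowing up the ratio.
#'
#' @param matrix An [expr_matrix()] on the log2 scale.
#' @param labels Named 0/1 vector over the samples (1 = positive class).
#' @return Named numeric vector of per-gene statistics, in matrix row order.
#' @export
signal_to_noise <- function(matrix, labels) {
  assert_expr_matrix(matrix, scale = "log2")
  labels <- assert_labels(labels, matrix)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stopf("each class needs at least 2 samples (got %d positive, %d negative)",
          sum(labels == 1L), sum(labels == 0L))
  }
  pos <- matrix$values[, labels == 1L, drop = FALSE]
  neg <- matrix$values[, labels == 0L, drop = FALSE]
  mu_p <- rowMeans(pos)
  mu_n <- rowMeans(neg)
  sd_p <- floor_sd(apply(pos, 1L, sd), mu_p)
  sd_n <- floor_sd(apply(neg, 1L, sd), mu_n)
  stat <- (mu_p - mu_n) / (sd_p + sd_n)
  names(stat) <- gene_ids(matrix)
  stat
}

floor_sd <- function(s, m) {
  fl <- 0.2 * abs(m)
  fl[fl == 0] <- 0.2
  pmax(s, fl)
}

#' Rank genes by a statistic, descending
#'
#' Ties are broken lexicographically by gene id so the ordering is
#' deterministic.
#'
#' @param statistic Named numeric vector (e.g. from [signal_to_noise()]).
#' @return A `ranked_genes` data.frame with columns `gene_id` and
#'   `statistic`, ordered by decreasing statistic.
#' @export
rank_genes <- function(statistic) {
  if (is.null(names(statistic)) || anyDuplicated(names(statistic))) {
    stopf("`statistic` must be named by unique gene ids")
  }
  ord <- order(-statistic, names(statistic), method = "radix")
  structure(data.frame(gene_id = names(statistic)[ord],
                       statistic = unname(statistic[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranked_genes", "data.frame"))
}

assert_ranked <- function(ranked) {
  if (!inherits(ranked, "ranked_genes")) {
    stopf("`ranked` must come from rank_genes()")
  }
  invisible(ranked)
}

#' Running-sum enrichment score of a gene set
#'
#' Walks the ranked gene list accumulating a running sum that rises at set
#' members and falls at non-members. Member increments are proportional to
#' `|statistic|^weight_exponent` normalized to total 1 over the members in
#' the universe; each non-member decrements by `1/(N - |S|)`. The
#' enrichment score is the (signed) maximum value the running sum attains,
#' so a set concentrated at the top of the list scores near 1 and a set
#' scattered uniformly scores near 0.
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_set Character vector of member gene ids; its intersection
#'   with the ranked universe must be non-empty and smaller than the
#'   universe.
#' @param weight_exponent Non-negative weight on `|statistic|`; 0 gives the
#'   classic unweighted (Kolmogorov-Smirnov-like) walk, 1 the weighted
#'   default.
#' @return A list of class `enrichment_result`: `set_name` (filled by
#'   callers), `ec_score`, `hit_positions` (ranks of members) and
#'   `running_sum`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  assert_ranked(ranked)
  if (!is.numeric(weight_exponent) || weight_exponent < 0) {
    stopf("`weight_exponent` must be non-negative")
  }
  n <- nrow(ranked)
  hits <- ranked$gene_id %in% gene_set
  n_hit <- sum(hits)
  if (n_hit == 0L) stopf("gene set has no members in the ranked universe")
  if (n_hit == n) {
    stopf("gene set covers the whole universe; the decrement is undefined")
  }
  w <- abs(ranked$statistic)^weight_exponent
  wsum <- sum(w[hits])
  steps <- numeric(n)
  if (wsum > 0) {
    steps[hits] <- w[hits] / wsum
  } else {
    steps[hits] <- 1 / n_hit  # all member weights zero: fall back to uniform
  }
  steps[!hits] <- -1 / (n - n_hit)
  rs <- cumsum(steps)
  structure(list(set_name = NA_character_, ec_score = max(rs),
                 hit_positions = which(hits), running_sum = rs),
            class = "enrichment_result")
}

#' Enrichment scores for a whole collection
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_sets Named list of gene sets; sets with no member in the
#'   universe are dropped (with a warning) rather than failing the batch.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return A data.frame with columns `set_name`, `ec_score` and `n_hits`.
#' @export
enrichment_scores <- function(ranked, gene_sets, weight_exponent = 1) {
  assert_ranked(ranked)
  if (length(gene_sets) == 0L || is.null(names(gene_sets))) {
    stopf("`gene_sets` must be a non-empty named list")
  }
  keep <- vapply(gene_sets, function(s) {
    k <- sum(ranked$gene_id %in% s)
    k > 0L && k < nrow(ranked)
  }, logical(1))
  if (!any(keep)) stopf("no gene set overlaps the ranked universe")
  if (!all(keep)) {
    warning(sprintf("dropping %d gene set(s) with empty or full overlap",
                    sum(!keep)), call. = FALSE)
  }
  res <- lapply(names(gene_sets)[keep], function(nm) {
    er <- enrichment_score(ranked, gene_sets[[nm]], weight_exponent)
    data.frame(set_name = nm, ec_score = er$ec_score,
               n_hits = length(er$hit_positions), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Screen the candidate feature panel
#'
#' Takes the top `n_per_tail` genes from the head of the ranked list (tagged
#' `over`, i.e. overexpressed in the positive class) and `n_per_tail` from
#' the tail (tagged `under`). When `restrict_to_sets` is on, eligibility is
#' limited to genes belonging to at least one gene set with a positive
#' enrichment score — the pathway-membership filter of the screening stage.
#' The panel is the genetic algorithm's search space: its length is the
#' chromosome dimension.
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_sets Optional named list of gene sets (required when
#'   `restrict_to_sets = TRUE`).
#' @param n_per_tail Candidates kept per tail (default 50, giving the
#'   100-gene panel).
#' @param restrict_to_sets Apply the positively-enriched-set membership
#'   filter. Defaults to `TRUE` when `gene_sets` is supplied.
#' @param weight_exponent Passed to [enrichment_scores()].
#' @return A `candidate_panel` data.frame with columns `gene_id`,
#'   `direction` (`"over"`/`"under"`) and `statistic`; `over` rows first.
#' @export
screen_candidates <- function(ranked, gene_sets = NULL, n_per_tail = 50,
                              restrict_to_sets = !is.null(gene_sets),
                              weight_exponent = 1) {
  assert_ranked(ranked)
  assert_count(n_per_tail, "n_per_tail", min = 1L)
  if (nrow(ranked) < 2L * n_per_tail) {
    stopf("ranked list has %d genes; need >= %d for two tails of %d",
          nrow(ranked), 2L * n_per_tail, n_per_tail)
  }
  eligible <- ranked
  if (isTRUE(restrict_to_sets)) {
    if (is.null(gene_sets)) {
      stopf("`restrict_to_sets = TRUE` requires `gene_sets`")
    }
    es <- enrichment_scores(ranked, gene_sets, weight_exponent)
    positive_sets <- es$set_name[es$ec_score > 0]
    members <- unique(unlist(gene_sets[positive_sets], use.names = FALSE))
    eligible <- ranked[ranked$gene_id %in% members, , drop = FALSE]
    if (nrow(eligible) < 2L * n_per_tail) {
      stopf(paste0("only %d genes belong to positively enriched sets; ",
                   "%d needed (shortfall %d)"),
            nrow(eligible), 2L * n_per_tail, 2L * n_per_tail - nrow(eligible))
    }
  }
  n_el <- nrow(eligible)
  over <- eligible[seq_len(n_per_tail), , drop = FALSE]
  under <- eligible[seq.int(n_el - n_per_tail + 1L, n_el), , drop = FALSE]
  panel <- rbind(cbind(over, direction = "over", stringsAsFactors = FALSE),
                 cbind(under, direction = "under", stringsAsFactors = FALSE))
  panel <- panel[, c("gene_id", "direction", "statistic")]
  rownames(panel) <- NULL
  structure(panel, class = c("candidate_panel", "data.frame"))
}

#' Subset an expression matrix to a candidate panel
#'
#' @param matrix An [expr_matrix()] containing all panel genes.
#' @param panel A [screen_candidates()] panel.
#' @return A numeric matrix (panel genes x samples) in panel row order.
#' @export
panel_matrix <- function(matrix, panel) {
  assert_expr_matrix(matrix)
  if (!inherits(panel, "candidate_panel")) {
    stopf("`panel` must be a candidate_panel")
  }
  missing <- setdiff(panel$gene_id, gene_ids(matrix))
  if (length(missing) > 0) {
    stopf("panel gene(s) absent from the matrix: %s",
          paste(missing, collapse = ", "))
  }
  matrix$values[panel$gene_id, , drop = FALSE]
}
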