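#' Read and write expression matrices as TSV
#'
#' The dialect is a plain tab-separated table whose first column is
#' `gene_id` and whose remaining columns are samples. The scale tag is not
#' part of the TSV; supply it on read (bundles written by
#' [write_fixture_bundle()] record it in `manifest.json`).
#'
#' @param path File path.
#' @param scale Scale tag to attach on read: `"linear"` or `"log2"`.
#' @return `read_expression_tsv()` returns an [expr_matrix()];
#'   `write_expression_tsv()` returns the path invisibly.
#' @export
read_expression_tsv <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "gene_id") {
    stopf("'%s' is not an expression TSV (first column must be gene_id)", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  expr_matrix(m, scale = scale)
}

#' @param matrix An [expr_matrix()] to write.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(matrix, path) {
  assert_expr_matrix(matrix)
  df <- data.frame(gene_id = gene_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write phenotype labels as CSV
#'
#' Two columns: `sample_id` and `label`, with label 1 for the positive class
#' and 0 for the negative class.
#'
#' @param path File path.
#' @return `read_labels_csv()` returns a named integer 0/1 vector.
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stopf("'%s' must have columns sample_id and label", path)
  }
  labels <- as.integer(df$label)
  names(labels) <- as.character(df$sample_id)
  assert_labels(labels)
}

#' @param labels Named 0/1 vector to write.
#' @rdname read_labels_csv
#' @export
write_labels_csv <- function(labels, path) {
  labels <- assert_labels(labels)
  if (is.null(names(labels))) stopf("`labels` must be named by sample id")
  write.csv(data.frame(sample_id = names(labels), label = labels,
                       stringsAsFactors = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Descriptions are kept
#' in a `descriptions` attribute on read and default to `"na"` on write.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("'%s' contains no gene sets", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stopf("malformed GMT line %d: need name, description and >= 1 member",
          which(bad)[1L])
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in '%s'", path)
  structure(sets, class = c("gene_set_collection", "list"),
            descriptions = vapply(fields, `[[`, character(1), 2L))
}

#' @param sets Named list of character vectors to write.
#' @param descriptions Optional character vector of per-set descriptions.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) == 0L || is.null(names(sets))) {
    stopf("`sets` must be a non-empty named list")
  }
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||% rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a candidate panel as TSV
#'
#' Columns: `gene_id`, `direction` (over/under) and the signal-to-noise
#' `statistic`.
#'
#' @param panel A candidate panel from [screen_candidates()].
#' @param path File path.
#' @export
write_panel_tsv <- function(panel, path) {
  if (!inherits(panel, "candidate_panel")) {
    stopf("`panel` must be a candidate_panel")
  }
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize a solution archive as TSV
#'
#' One row per retained top-ranked solution:
#' `measure<TAB>rank<TAB>fitness<TAB>bitstring`. Fitness is written in full
#' precision (`%.17g`) so archives from identical seeds are byte-identical
#' and lossless.
#'
#' @param archive A solution archive from [run_selection_procedure()].
#' @param path File path.
#' @export
write_archive_tsv <- function(archive, path) {
  if (!inherits(archive, "solution_archive")) {
    stopf("`archive` must be a solution_archive")
  }
  rows <- character()
  for (m in names(archive$measures)) {
    top <- archive$measures[[m]]$top
    if (nrow(top$bits) == 0L) next
    rows <- c(rows, vapply(seq_len(nrow(top$bits)), function(q) {
      sprintf("%s\t%d\t%.17g\t%s", m, q, top$fitness[q],
              paste(top$bits[q, ], collapse = ""))
    }, character(1)))
  }
  writeLines(c("measure\trank\tfitness\tbitstring", rows), path)
  invisible(path)
}
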