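#' Expression matrix with a scale tag
#'
#' A light container for a genes x samples numeric matrix that records
#' whether values are raw linear intensities or log2-transformed. The tag is
#' what lets [linear_scale()] and [log2_transform()] refuse to run on data of
#' the wrong scale (e.g. guard against double log-transformation).
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (unique colnames = sample ids). All values must be
#'   finite; linear-scale values must be non-negative.
#' @param scale Either `"linear"` (raw intensities) or `"log2"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `scale` (the tag).
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' em <- expr_matrix(m, scale = "linear")
#' dim(em)
#' @export
expr_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stopf("`values` must have at least one gene and one sample")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || any(gid == "") || anyDuplicated(gid)) {
    stopf("rownames(values) must be unique, non-missing gene ids")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "") || anyDuplicated(sid)) {
    stopf("colnames(values) must be unique, non-missing sample ids")
  }
  if (!all(is.finite(values))) stopf("expression values must all be finite")
  if (scale == "linear" && any(values < 0)) {
    stopf("linear-scale intensities must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

assert_expr_matrix <- function(x, scale = NULL, arg = "matrix") {
  if (!inherits(x, "expr_matrix")) stopf("`%s` must be an expr_matrix", arg)
  if (!is.null(scale) && x$scale != scale) {
    stopf("`%s` is on the %s scale; %s scale required", arg, x$scale, scale)
  }
  invisible(x)
}

# Phenotype labels: named 0/1 integer vector aligned with the matrix columns.
# Positive class (1) is the class of interest (GBM in the motivating design).
assert_labels <- function(labels, em = NULL) {
  if (is.factor(labels)) labels <- as.integer(as.character(labels))
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    stopf("`labels` must be a vector of 0 (negative) and 1 (positive)")
  }
  nm <- names(labels)
  labels <- as.integer(labels)
  names(labels) <- nm
  if (!is.null(em)) {
    if (length(labels) != ncol(em$values)) {
      stopf("`labels` length (%d) must match the number of samples (%d)",
            length(labels), ncol(em$values))
    }
    nm <- names(labels)
    if (!is.null(nm)) {
      if (!identical(nm, sample_ids(em))) {
        if (!setequal(nm, sample_ids(em))) {
          stopf("label names do not match sample ids")
        }
        labels <- labels[sample_ids(em)]
      }
    } else {
      names(labels) <- sample_ids(em)
    }
  }
  labels
}
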