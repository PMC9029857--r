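#' Per-array trimmed-mean linear scaling
#'
#' Normalizes a raw linear-intensity matrix so that every array (sample) has
#' the same two-sided trimmed mean, the `target_intensity`. Each sample is
#' multiplied by a single factor `target / trimmed_mean(sample)`; nothing
#' else is altered, so within-sample structure (and rank order) is
#' preserved exactly. This is the classic global-scaling normalization used
#' for single-channel microarrays (conventional target signal 500, trim
#' 2%).
#'
#' @param matrix An [expr_matrix()] on the linear scale.
#' @param target_intensity Common trimmed mean after scaling.
#' @param trim_fraction Fraction trimmed from each tail before averaging
#'   (`0 <= trim_fraction < 0.5`).
#' @return A linear-scale [expr_matrix()] whose per-sample trimmed means all
#'   equal `target_intensity`.
#' @examples
#' m <- matrix(c(1:10, 2 * (1:10)), ncol = 2,
#'             dimnames = list(sprintf("G%02d", 1:10), c("A", "B")))
#' scaled <- linear_scale(expr_matrix(m, "linear"), 500, 0.1)
#' mean(scaled$values[, 1], trim = 0.1)
#' @export
linear_scale <- function(matrix, target_intensity = 500, trim_fraction = 0.02) {
  assert_expr_matrix(matrix, scale = "linear")
  if (!is.numeric(target_intensity) || target_intensity <= 0) {
    stopf("`target_intensity` must be positive")
  }
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5) {
    stopf("`trim_fraction` must be in [0, 0.5)")
  }
  tm <- apply(matrix$values, 2L, mean, trim = trim_fraction)
  zero <- tm <= 0
  if (any(zero)) {
    stopf("cannot scale sample '%s': trimmed mean is zero",
          sample_ids(matrix)[which(zero)[1L]])
  }
  scaled <- sweep(matrix$values, 2L, target_intensity / tm, `*`)
  expr_matrix(scaled, scale = "linear")
}

#' Floored log2 transformation
#'
#' `value -> log2(max(value, floor))`. The floor (default 1) maps zero and
#' sub-floor intensities to `log2(floor)` (0 at the default) instead of
#' minus infinity. Refuses to run on matrices already tagged log2, guarding
#' against double transformation.
#'
#' @param matrix An [expr_matrix()] on the linear scale.
#' @param floor Positive lower clamp applied before taking logs.
#' @return An [expr_matrix()] tagged log2.
#' @examples
#' m <- matrix(c(0, 1024, 500, 2), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("A", "B")))
#' log2_transform(expr_matrix(m, "linear"))$values
#' @export
log2_transform <- function(matrix, floor = 1) {
  if (inherits(matrix, "expr_matrix") && matrix$scale == "log2") {
    stopf("matrix is already log2-transformed")
  }
  assert_expr_matrix(matrix, scale = "linear")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stopf("`floor` must be a single positive number")
  }
  expr_matrix(log2(pmax(matrix$values, floor)), scale = "log2")
}
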