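#' Confusion counts for a binary classifier
#'
#' The four cells of a 2x2 confusion table, with the phenotype of interest
#' (e.g. GBM) as the positive class. All four fitness measures used by the
#' genetic algorithm are pure functions of this object (plus, for the hybrid
#' measure, the class balance).
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives. Their sum must be >= 1.
#' @return An object of class `confusion_counts`.
#' @examples
#' cc <- confusion_counts(tp = 50, tn = 40, fp = 10, fn = 5)
#' accuracy(cc)
#' mcc(cc)
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  for (nm in c("tp", "tn", "fp", "fn")) assert_count(get(nm), nm)
  x <- c(tp = as.double(tp), tn = as.double(tn),
         fp = as.double(fp), fn = as.double(fn))
  if (sum(x) < 1) stopf("confusion counts must total at least 1")
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%g tn=%g fp=%g fn=%g\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Class balance for the hybrid fitness measure
#'
#' @param n_pos,n_neg Number of positive- and negative-class samples;
#'   `n_neg` must be >= 1.
#' @return An object of class `class_balance` with `delta = n_pos / n_neg`,
#'   the weight applied to specificity in [hybrid_score()].
#' @examples
#' class_balance(228, 148)$delta
#' @export
class_balance <- function(n_pos, n_neg) {
  assert_count(n_pos, "n_pos", min = 1L)
  assert_count(n_neg, "n_neg", min = 1L)
  structure(list(n_pos = as.double(n_pos), n_neg = as.double(n_neg),
                 delta = n_pos / n_neg),
            class = "class_balance")
}

as_cc <- function(cc) {
  if (!inherits(cc, "confusion_counts")) {
    stopf("expected a confusion_counts object")
  }
  cc
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cc A [confusion_counts()] object.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cc) {
  cc <- as_cc(cc)
  (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the correlation
#' between binary truth and prediction. When any margin of the confusion
#' table is zero the denominator vanishes and the value is taken as 0 (the
#' chance-level convention), which keeps genetic-algorithm fitness totally
#' ordered when a chromosome yields one-class predictions.
#'
#' @param cc A [confusion_counts()] object.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cc) {
  cc <- as_cc(cc)
  den2 <- (cc$tp + cc$fp) * (cc$tp + cc$fn) * (cc$tn + cc$fp) * (cc$tn + cc$fn)
  if (den2 == 0) return(0)
  (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(den2)
}

#' F1 score
#'
#' Harmonic mean of precision `TP/(TP+FP)` and sensitivity `TP/(TP+FN)`.
#' Returns 0 when TP = 0 (precision or sensitivity undefined or zero).
#'
#' @param cc A [confusion_counts()] object.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(cc) {
  cc <- as_cc(cc)
  if (cc$tp == 0) return(0)
  precision <- cc$tp / (cc$tp + cc$fp)
  sensitivity <- cc$tp / (cc$tp + cc$fn)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Hybrid fitness: sensitivity plus weighted specificity
#'
#' `Sensitivity + delta * Specificity`, where `delta` is the ratio of
#' positive to negative samples. The weighting counteracts the tendency of
#' sensitivity-driven fitness to ignore the minority class when classes are
#' unbalanced. Undefined margins (no actual positives or no actual
#' negatives) contribute 0.
#'
#' @param cc A [confusion_counts()] object.
#' @param balance A [class_balance()] object supplying `delta`.
#' @return Value in \[0, 1 + delta\].
#' @export
hybrid_score <- function(cc, balance) {
  cc <- as_cc(cc)
  if (!inherits(balance, "class_balance")) {
    stopf("`balance` must be a class_balance object")
  }
  sens <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
  spec <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else 0
  sens + balance$delta * spec
}

# Vectorized metric evaluation over a grid of pooled confusion counts
# (rows: tp, tn, fp, fn). Used on the SVM grid where each (cost, gamma)
# point contributes one pooled out-of-fold confusion table.
metric_from_counts <- function(counts, measure, delta = 1) {
  tp <- counts[, 1L]; tn <- counts[, 2L]; fp <- counts[, 3L]; fn <- counts[, 4L]
  switch(measure,
    acc = (tp + tn) / (tp + tn + fp + fn),
    mcc = {
      den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      out <- ifelse(den2 == 0, 0, (tp * tn - fp * fn) / sqrt(pmax(den2, 1)))
      as.numeric(out)
    },
    f1 = {
      out <- ifelse(tp == 0, 0, 2 * tp / (2 * tp + fp + fn))
      as.numeric(out)
    },
    hybrid = {
      sens <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
      spec <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
      as.numeric(sens + delta * spec)
    },
    stopf("unknown measure '%s'", measure)
  )
}

MEASURES <- c("acc", "mcc", "f1", "hybrid")

# Minimum attainable value of each measure; used as the sentinel fitness for
# the all-zero chromosome so it can never displace a valid solution.
measure_floor <- function(measure) {
  switch(measure, acc = 0, mcc = -1, f1 = 0, hybrid = 0,
         stopf("unknown measure '%s'", measure))
}
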