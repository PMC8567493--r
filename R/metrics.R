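# Classification metrics: AUC, per-class precision/sensitivity/F-1.

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted one half (midrank estimator; equals the trapezoidal area
#' under the ROC curve).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical, 0/1, or two-level factor; the positive class is
#'   `TRUE`, `1`, or the second factor level.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) > 2) stop("labels must be binary")
  labels == u[length(u)]
}

#' Per-class precision, sensitivity and F-1
#'
#' F-1 is the harmonic mean of precision and sensitivity; a zero
#' denominator in any of the three yields 0 with a warning.
#'
#' @param predicted Predicted class labels.
#' @param labels True class labels.
#' @param positive_class The class treated as positive.
#' @return Named numeric `c(precision, sensitivity, f1)`.
#' @export
class_metrics <- function(predicted, labels, positive_class) {
  pp <- predicted == positive_class
  pl <- labels == positive_class
  tp <- sum(pp & pl); fp <- sum(pp & !pl); fn <- sum(!pp & pl)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      0
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  sensitivity <- safe(tp, tp + fn, "sensitivity")
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  c(precision = precision, sensitivity = sensitivity, f1 = f1)
}

# assemble a model evaluation record from pooled scores and labels
eval_from_scores <- function(scores, labels, positive_class, threshold = 0.5) {
  lev <- levels(labels)
  predicted <- factor(lev[1 + (scores >= threshold)], levels = lev)
  list(auc = auc(scores, labels == positive_class),
       accuracy = mean(predicted == labels),
       class1 = class_metrics(predicted, labels, lev[1]),
       class2 = class_metrics(predicted, labels, lev[2]))
}
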