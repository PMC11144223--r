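#' Confusion counts for a binary classifier
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives at the window level
#'   (an "AHI event" window is the positive class).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_validation("confusion counts must be non-negative finite numbers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Threshold-level binary classification metrics
#'
#' Accuracy, recall (sensitivity), specificity, precision and F1 from a
#' confusion table. Ratios with a zero denominator (e.g. precision with no
#' predicted positives) are returned as 0 and flagged in the `undefined`
#' attribute rather than propagating NaN.
#'
#' @param counts A `confusion_counts` object, or a list with elements
#'   `tp`, `tn`, `fp`, `fn`.
#' @return Named list with `accuracy`, `recall`, `specificity`,
#'   `precision`, `f1`, and an `undefined` character vector naming any
#'   0/0 metrics.
#' @export
binary_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts$tp, counts$tn, counts$fp, counts$fn)
  }
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  acc <- ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  rec <- ratio(tp, tp + fn, "recall")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  f1 <- if (prec + rec == 0) {
    undefined <- c(undefined, "f1")
    0
  } else {
    2 * (prec * rec) / (prec + rec)
  }
  list(accuracy = acc, recall = rec, specificity = spec,
       precision = prec, f1 = f1, undefined = undefined)
}

check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop_validation("labels must be binary (0/1)")
  }
  if (length(unique(labels)) < 2L) {
    stop_validation("both classes must be present")
  }
  labels
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney U) formulation, so tied scores
#' count one half. Equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary 0/1 labels.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Precision/recall pairs at every distinct score threshold, highest first.
pr_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)  # last point at each distinct threshold
  tp <- tp[keep]; fp <- fp[keep]
  n_pos <- sum(labels)
  data.frame(threshold = s[keep],
             precision = tp / (tp + fp),
             recall = tp / n_pos)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average precision): each increment of recall is
#' weighted by the precision attained at that threshold. Step rather than
#' linear interpolation avoids the optimistic bias of trapezoids on PR
#' curves.
#'
#' @inheritParams roc_auc
#' @export
pr_auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  pts <- pr_points(scores, labels)
  d_recall <- diff(c(0, pts$recall))
  sum(d_recall * pts$precision)
}

SEVERITY_LEVELS <- c("healthy", "mild", "moderate", "severe")

#' Macro F1 and agreement statistics over the four AHI severity classes
#'
#' One-vs-rest F1 per class, averaged without class weights, plus the
#' exact-agreement fraction and the within-one-class fraction under the
#' ordering healthy < mild < moderate < severe.
#'
#' @param true_classes,predicted_classes Character or factor vectors over
#'   `c("healthy", "mild", "moderate", "severe")`.
#' @return List with `macro_f1`, `per_class_f1`, `confusion` (4x4 matrix,
#'   rows = truth), `exact_agreement`, `within_one`.
#' @export
f1_ahi <- function(true_classes, predicted_classes) {
  stopifnot(length(true_classes) == length(predicted_classes))
  tc <- as.character(true_classes); pc <- as.character(predicted_classes)
  if (!all(c(tc, pc) %in% SEVERITY_LEVELS)) {
    stop_validation("severity labels must be one of: ",
                    paste(SEVERITY_LEVELS, collapse = ", "))
  }
  tf <- factor(tc, levels = SEVERITY_LEVELS)
  pf <- factor(pc, levels = SEVERITY_LEVELS)
  confusion <- table(truth = tf, predicted = pf)
  per_class <- vapply(SEVERITY_LEVELS, function(cl) {
    m <- binary_metrics(confusion_counts(
      tp = sum(tc == cl & pc == cl),
      tn = sum(tc != cl & pc != cl),
      fp = sum(tc != cl & pc == cl),
      fn = sum(tc == cl & pc != cl)
    ))
    m$f1
  }, numeric(1))
  dist <- abs(as.integer(tf) - as.integer(pf))
  list(macro_f1 = mean(per_class),
       per_class_f1 = per_class,
       confusion = unclass(confusion),
       exact_agreement = mean(dist == 0L),
       within_one = mean(dist <= 1L))
}
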