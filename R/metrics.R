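#' Confusion counts
#'
#' Container for the four cells of a binary confusion table at one decision
#' threshold.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cnt <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    rlang::abort("confusion counts must be nonnegative integers",
                 class = "gcnprio_config_error")
  }
  structure(as.list(cnt), class = "confusion_counts")
}

undefined_metric <- function(what) {
  rlang::warn(sprintf("%s is undefined for these counts", what),
              class = "gcnprio_undefined_metric")
  NA_real_
}

#' Precision, recall and false-positive rate
#'
#' The threshold metrics underlying the ROC and precision-recall curves:
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' FPR = FP / (FP + TN). When a denominator is zero the metric is undefined:
#' a warning of class `gcnprio_undefined_metric` is raised and `NA` returned
#' (the curve constructors substitute the conventional precision of 1 at the
#' zero-prediction end).
#'
#' @param c A [confusion_counts()].
#' @return A number in `[0, 1]`, or `NA` with a warning.
#' @name threshold_metrics
NULL

#' @rdname threshold_metrics
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) return(undefined_metric("precision"))
  c$tp / (c$tp + c$fp)
}

#' @rdname threshold_metrics
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) return(undefined_metric("recall"))
  c$tp / (c$tp + c$fn)
}

#' @rdname threshold_metrics
#' @export
fpr <- function(c) {
  if (c$fp + c$tn == 0) return(undefined_metric("false-positive rate"))
  c$fp / (c$fp + c$tn)
}

check_curve_input <- function(predictions) {
  predictions <- as.data.frame(predictions)
  if (!all(c("y_true", "p_positive") %in% names(predictions))) {
    rlang::abort("predictions need `y_true` and `p_positive` columns",
                 class = "gcnprio_shape_error")
  }
  y <- as.integer(predictions$y_true)
  if (length(unique(y)) < 2L) {
    rlang::abort("curve construction needs at least one positive and one negative",
                 class = "gcnprio_single_class_error")
  }
  list(y = y, p = as.numeric(predictions$p_positive))
}

# cumulative TP/FP at every distinct score threshold, scores descending; ties
# collapse into a single threshold step
threshold_sweep <- function(y, p) {
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]
  p <- p[ord]
  last_of_tie <- c(p[-1] != p[-length(p)], TRUE)
  tibble::tibble(
    threshold = p[last_of_tie],
    tp = cumsum(y)[last_of_tie],
    fp = cumsum(1 - y)[last_of_tie]
  )
}

new_metric_curve <- function(points, kind) {
  structure(points, kind = kind,
            class = c("metric_curve", class(tibble::tibble())))
}

#' ROC curve points
#'
#' Sweeps a decision threshold over every distinct predicted score and records
#' (false-positive rate, recall) at each step, anchored at (0, 0) and (1, 1).
#' Tied scores form a single threshold step.
#'
#' @param predictions Data frame with `y_true` (0/1) and `p_positive` columns;
#'   both classes must be present.
#' @return A `metric_curve` tibble with columns `threshold`, `x` (FPR), `y`
#'   (recall), and attribute `kind = "roc"`.
#' @export
roc_points <- function(predictions) {
  d <- check_curve_input(predictions)
  sw <- threshold_sweep(d$y, d$p)
  n_pos <- sum(d$y)
  n_neg <- length(d$y) - n_pos
  pts <- tibble::tibble(
    threshold = c(Inf, sw$threshold),
    x = c(0, sw$fp / n_neg),
    y = c(0, sw$tp / n_pos)
  )
  new_metric_curve(pts, "roc")
}

#' Precision-recall curve points
#'
#' Records (recall, precision) at every distinct threshold, with the
#' zero-prediction end anchored at recall 0 and precision 1 by the usual
#' convention.
#'
#' @inheritParams roc_points
#' @return A `metric_curve` tibble with columns `threshold`, `x` (recall), `y`
#'   (precision), and attribute `kind = "pr"`.
#' @export
pr_points <- function(predictions) {
  d <- check_curve_input(predictions)
  sw <- threshold_sweep(d$y, d$p)
  n_pos <- sum(d$y)
  pts <- tibble::tibble(
    threshold = c(Inf, sw$threshold),
    x = c(0, sw$tp / n_pos),
    y = c(1, sw$tp / (sw$tp + sw$fp))
  )
  new_metric_curve(pts, "pr")
}

#' Area under a metric curve by trapezoidal integration
#'
#' For ROC curves the result equals the tie-corrected Mann-Whitney statistic
#' (the probability that a random positive outscores a random negative, ties
#' counted one half). For precision-recall curves it integrates over the
#' achieved points without interpolation.
#'
#' @param curve A `metric_curve` (or any data frame with nondecreasing `x` and
#'   `y` columns, at least two rows).
#' @return Area in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  x <- curve$x
  y <- curve$y
  if (length(x) < 2L) {
    rlang::abort("a curve needs at least two points", class = "gcnprio_shape_error")
  }
  if (is.unsorted(x)) {
    rlang::abort("curve x values must be nondecreasing",
                 class = "gcnprio_curve_order_error")
  }
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# per-fold convenience: AUC and AUPR from a prediction table
fold_metrics <- function(predictions) {
  c(auc = auc_trapezoid(roc_points(predictions)),
    aupr = auc_trapezoid(pr_points(predictions)))
}

#' Write curve points to a TSV file
#'
#' @param curve A `metric_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a ROC or precision-recall curve
#'
#' @param object A `metric_curve` from [roc_points()] or [pr_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_curve
#' @export
autoplot.metric_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  labs <- if (identical(kind, "roc")) {
    c("False-positive rate", "Recall (TPR)", "ROC curve")
  } else {
    c("Recall", "Precision", "Precision-recall curve")
  }
  ggplot2::ggplot(as.data.frame(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = labs[1], y = labs[2], title = labs[3]) +
    ggplot2::theme_minimal()
}
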