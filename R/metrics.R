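# Confusion-matrix segmentation metrics. TP/FP/TN/FN are pixel tallies;
# accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
# dice = 2TP/(2TP+FP+FN), iou = TP/(TP+FP+FN), and F1 from one confusion
# matrix is algebraically identical to dice (differences can only come from
# the aggregation mode).

#' Pixel-wise confusion counts
#'
#' @param pred,truth Binary HxW matrices (values exactly 0/1) of identical
#'   size.
#' @return Object of class `confusion_counts`: named numeric vector
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop(sprintf("prediction is %s but truth is %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(truth), collapse = "x")), call. = FALSE)
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("masks must be strictly binary (0/1)", call. = FALSE)
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(c(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g FP=%g TN=%g FN=%g (n=%g)\n",
              x["TP"], x["FP"], x["TN"], x["FN"], sum(x)))
  invisible(x)
}

as_counts <- function(x) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(x)))
  x
}

#' Metrics from confusion counts
#'
#' Computes accuracy, precision, recall, F1, Dice and IoU from one set of
#' confusion counts. When prediction and truth are both empty (TP+FP+FN=0),
#' the overlap metrics are scored per `degenerate`: `"one"` (default, a
#' correctly-empty prediction is perfect) or `"na"`.
#'
#' @param c A `confusion_counts` object (or named vector with TP/FP/TN/FN).
#' @param degenerate Score for overlap metrics on empty-vs-empty slices.
#' @return One-row tibble (class `metric_report`) with the six metrics plus
#'   `aggregation` and `n_slices`.
#' @export
compute_metrics <- function(c, degenerate = c("one", "na")) {
  degenerate <- match.arg(degenerate)
  c <- as_counts(c)
  if (sum(c) == 0) stop("all confusion counts are zero", call. = FALSE)
  tp <- c[["TP"]]; fp <- c[["FP"]]; tn <- c[["TN"]]; fn <- c[["FN"]]
  degen <- if (degenerate == "one") 1 else NA_real_
  div <- function(num, den) if (den == 0) degen else num / den
  acc <- (tp + tn) / (tp + fp + tn + fn)
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  dice <- div(2 * tp, 2 * tp + fp + fn)
  iou <- div(tp, tp + fp + fn)
  report <- tibble::tibble(
    accuracy = acc, precision = prec, recall = rec,
    f1 = dice, dice = dice, iou = iou,
    aggregation = "micro", n_slices = 1L
  )
  class(report) <- c("metric_report", class(report))
  report
}

#' Aggregate metrics over many slices
#'
#' `"micro"` sums the confusion counts first and computes metrics once;
#' `"per_slice_mean"` computes metrics per slice and averages them. The two
#' generally differ (which is how a report can show F1 unequal to Dice even
#' though they coincide on any single confusion matrix).
#'
#' @param counts_list List of `confusion_counts`.
#' @param mode `"micro"` or `"per_slice_mean"`.
#' @param degenerate Passed to [compute_metrics()].
#' @return One-row `metric_report` tibble.
#' @export
aggregate_metrics <- function(counts_list,
                              mode = c("micro", "per_slice_mean"),
                              degenerate = "one") {
  mode <- match.arg(mode)
  if (length(counts_list) == 0L) {
    stop("no confusion counts to aggregate", call. = FALSE)
  }
  if (inherits(counts_list, "confusion_counts")) {
    counts_list <- list(counts_list)
  }
  if (mode == "micro") {
    tot <- Reduce(`+`, lapply(counts_list, as_counts))
    report <- compute_metrics(structure(tot, class = "confusion_counts"),
                              degenerate)
  } else {
    per <- lapply(counts_list, compute_metrics, degenerate = degenerate)
    cols <- c("accuracy", "precision", "recall", "f1", "dice", "iou")
    report <- tibble::as_tibble(
      lapply(setNames(cols, cols),
             function(cl) mean(vapply(per, function(r) r[[cl]], numeric(1)),
                               na.rm = TRUE)))
    report$aggregation <- "per_slice_mean"
    class(report) <- c("metric_report", class(report))
  }
  report$aggregation <- mode
  report$n_slices <- length(counts_list)
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> (%s, %d slice%s)\n", x$aggregation[1],
              x$n_slices[1], if (x$n_slices[1] == 1L) "" else "s"))
  NextMethod()
}
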