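#' Mean absolute error between two power traces
#'
#' @param truth,pred [power_series()] (or plain numeric vectors) of equal
#'   length.
#' @return Mean absolute deviation in watts.
#' @export
mae <- function(truth, pred) {
  y <- if (inherits(truth, "power_series")) truth$values else as.numeric(truth)
  yhat <- if (inherits(pred, "power_series")) pred$values else as.numeric(pred)
  if (length(y) != length(yhat) || length(y) == 0L) {
    stop("contract error: series lengths differ (", length(y), " vs ",
         length(yhat), ")")
  }
  mean(abs(y - yhat))
}

#' Precision, recall and f1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and f1 their
#' harmonic mean.  A zero denominator yields 0 for the affected metric,
#' with a warning.
#'
#' @param counts List or vector with elements `TP`, `FP`, `FN` (optionally
#'   `TN`), all non-negative.
#' @return List of class `classification_metrics`: `precision`, `recall`,
#'   `f1`.
#' @export
classification_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) stop("contract error: negative counts")
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("TP + FP = 0; precision reported as 0")
    0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("TP + FN = 0; recall reported as 0")
    0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f, recall %.3f, f1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Sample-level ON/OFF confusion between truth and prediction
#'
#' Both traces are thresholded into operational states and compared per
#' sample; positives are ON states.
#'
#' @param truth,pred Aligned [power_series()].
#' @param threshold ON threshold in watts.
#' @return List: `TP`, `FP`, `FN`, `TN`.
#' @export
state_confusion <- function(truth, pred, threshold = 500) {
  y <- derive_states(truth, threshold)$states
  yhat <- derive_states(pred, threshold)$states
  if (length(y) != length(yhat)) stop("contract error: series lengths differ")
  list(TP = sum(y & yhat), FP = sum(!y & yhat),
       FN = sum(y & !yhat), TN = sum(!y & !yhat))
}

#' Day-level confusion between monitoring decisions and injected labels
#'
#' Positives are anomalous days.  A predicted day is positive when its
#' decision is `"anomalous"`; a labelled day is positive when its label is
#' neither `"normal"` nor `"data_gap"`.  Days labelled `"data_gap"` are
#' excluded from the counts.
#'
#' @param predicted Data frame with columns `date` and `decision`.
#' @param labels Data frame with columns `date` and `label`; must cover
#'   exactly the predicted days (after the data-gap exclusion).
#' @return List: `TP`, `FP`, `FN`, `TN`.
#' @export
day_level_confusion <- function(predicted, labels) {
  labels <- labels[labels$label != "data_gap", , drop = FALSE]
  predicted <- predicted[predicted$date %in% labels$date, , drop = FALSE]
  missing_pred <- setdiff(as.character(labels$date),
                          as.character(predicted$date))
  missing_lab <- setdiff(as.character(predicted$date),
                         as.character(labels$date))
  if (length(missing_pred) || length(missing_lab)) {
    stop("day sets differ; unpredicted: ",
         paste(missing_pred, collapse = ", "), "; unlabelled: ",
         paste(missing_lab, collapse = ", "))
  }
  lab <- labels$label[match(predicted$date, labels$date)]
  pos_true <- lab != "normal"
  pos_pred <- predicted$decision == "anomalous"
  list(TP = sum(pos_true & pos_pred), FP = sum(!pos_true & pos_pred),
       FN = sum(pos_true & !pos_pred), TN = sum(!pos_true & !pos_pred))
}
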