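# The evaluation battery: confusion counts, Sn/Sp/accuracy/MCC, ROC/AUC and
# mean +/- SD aggregation across folds. +1 (GPCR) is the positive class.

#' Confusion-matrix counts
#'
#' @param truth true labels over \{+1, -1\}.
#' @param predicted predicted labels over \{+1, -1\}; same length.
#' @return a `gpcr_confusion` list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("truth and predicted lengths differ")
  if (length(truth) == 0L) stop("empty input")
  if (!all(truth %in% c(-1, 1)) || !all(predicted %in% c(-1, 1))) {
    stop("labels must be +1 or -1")
  }
  structure(list(tp = sum(truth == 1 & predicted == 1),
                 tn = sum(truth == -1 & predicted == -1),
                 fp = sum(truth == -1 & predicted == 1),
                 fn = sum(truth == 1 & predicted == -1)),
            class = "gpcr_confusion")
}

#' @export
print.gpcr_confusion <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, weighted accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, balanced accuracy `(Sn+Sp)/2` and Matthews
#' correlation. Both accuracy variants are always reported because reported
#' GPCR-prediction accuracies mix the two conventions. A metric whose
#' denominator is empty is `NA` and named in `$undefined`; MCC with a zero
#' marginal is 0 by convention, also flagged.
#'
#' @param cm a [confusion()] result, or a list/vector with tp, tn, fp, fn.
#' @return a list with `sn`, `sp`, `acc_weighted`, `acc_balanced`, `mcc` and
#'   a character vector `undefined`.
#' @export
classification_metrics <- function(cm) {
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  undefined <- character(0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sn"); NA_real_ }
  sp <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "sp"); NA_real_ }
  total <- tp + tn + fp + fn
  acc_w <- if (total > 0) (tp + tn) / total else { undefined <- c(undefined, "acc_weighted"); NA_real_ }
  acc_b <- if (!is.na(sn) && !is.na(sp)) (sn + sp) / 2 else { undefined <- c(undefined, "acc_balanced"); NA_real_ }
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else {
    undefined <- c(undefined, "mcc_zero_marginal")
    0
  }
  list(sn = sn, sp = sp, acc_weighted = acc_w, acc_balanced = acc_b,
       mcc = mcc, undefined = undefined)
}

#' ROC curve and AUC from scores
#'
#' Thresholds sweep from high to low scores, tied scores advancing the curve
#' in a single step; the curve starts at (0,0) and ends at (1,1). AUC is the
#' trapezoidal area, which equals the Mann-Whitney probability that a random
#' positive outscores a random negative, ties counted one half.
#'
#' @param truth labels over \{+1, -1\}; both classes must be present.
#' @param scores numeric scores, larger = more positive.
#' @return a list with `auc` and `roc_points` (a data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("truth and scores lengths differ")
  if (!all(truth %in% c(-1, 1))) stop("labels must be +1 or -1")
  npos <- sum(truth == 1); nneg <- sum(truth == -1)
  if (npos == 0L || nneg == 0L) stop("ROC requires both classes in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  step_ends <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(t == 1)[step_ends] / npos)
  fpr <- c(0, cumsum(t == -1)[step_ends] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Evaluate predictions against truth
#'
#' Bundles the confusion counts, threshold metrics and ROC/AUC for one test
#' set.
#'
#' @param truth labels over \{+1, -1\}.
#' @param scores positive-class scores in \[0, 1\].
#' @param labels predicted labels; defaults to `score >= 0.5`.
#' @return an object of class `gpcr_eval`.
#' @export
evaluate_predictions <- function(truth, scores, labels = NULL) {
  if (is.null(labels)) labels <- ifelse(scores >= 0.5, 1L, -1L)
  cm <- confusion(truth, labels)
  m <- classification_metrics(cm)
  roc <- roc_auc(truth, scores)
  structure(c(list(confusion = cm), m[c("sn", "sp", "acc_weighted", "acc_balanced", "mcc")],
              list(undefined = m$undefined, auc = roc$auc, roc_points = roc$roc_points)),
            class = "gpcr_eval")
}

#' @export
print.gpcr_eval <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d\n",
              x$confusion$tp, x$confusion$fn, x$confusion$tn, x$confusion$fp))
  cat(sprintf("Sn %.4f  Sp %.4f  Acc(weighted) %.4f  Acc(balanced) %.4f  MCC %.4f  AUC %.4f\n",
              x$sn, x$sp, x$acc_weighted, x$acc_balanced, x$mcc, x$auc))
  invisible(x)
}

eval_metric_names <- c("sn", "sp", "acc_weighted", "acc_balanced", "mcc", "auc")

#' Per-metric mean and sample SD
#'
#' @param tbl a data.frame of per-fold metric values (numeric columns).
#' @return a data.frame with one row per column of `tbl` and columns
#'   `metric`, `mean`, `sd` (sample SD, n-1 denominator).
#' @export
aggregate_metrics <- function(tbl) {
  if (nrow(tbl) < 2L) stop("aggregation needs at least 2 folds")
  num <- tbl[vapply(tbl, is.numeric, logical(1))]
  data.frame(metric = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate per-fold evaluation reports
#'
#' @param reports a list of at least 2 `gpcr_eval` objects.
#' @return a data.frame of per-metric mean and sample SD.
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) < 2L) stop("aggregation needs at least 2 reports")
  tbl <- as.data.frame(lapply(stats::setNames(eval_metric_names, eval_metric_names),
                              function(m) vapply(reports, `[[`, numeric(1), m)))
  aggregate_metrics(tbl)
}
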