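# Stratified k-fold cross-validation of the full pipeline:
# split -> SMOTE on the training partition -> Random Forest -> evaluation.

#' Cross-validate the GPCR classifier
#'
#' Runs the complete evaluation protocol on a labeled feature dataset:
#' stratified k-fold splitting, SMOTE rebalancing of each training partition
#' (test partitions are never touched), Random-Forest training and per-fold
#' evaluation with Sn, Sp, both accuracy variants, MCC and AUC, aggregated as
#' mean and sample SD. Deterministic given `seed`.
#'
#' @param data a labeled `gpcr_dataset` with both classes.
#' @param k number of folds (default 5).
#' @param smote_percent SMOTE amount as a multiple of 100 (default 300,
#'   i.e. three synthetic vectors per minority original; 0 disables
#'   rebalancing).
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param n_trees,max_features,min_leaf forest settings, see [forest_config()].
#' @param seed integer seed driving the split, SMOTE and forest stages.
#' @return an object of class `gpcr_cv`: `folds` (per-fold `gpcr_eval`
#'   reports), `table` (per-fold metric data.frame), `summary` (mean/SD per
#'   metric) and `config`.
#' @export
gpcr_crossval <- function(data, k = 5, smote_percent = 300, k_neighbors = 5,
                          n_trees = 100, max_features = "sqrt", min_leaf = 1,
                          seed = 1) {
  folds <- make_folds(data, k = k, seed = seed)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    split <- folds[[i]]
    if (smote_percent > 0) {
      split <- rebalance_training(split,
        smote_config(percent = smote_percent, k_neighbors = k_neighbors,
                     seed = derive_seed(seed, 100L + i)))
    }
    model <- gpcr_rf(split$train,
      forest_config(n_trees = n_trees, max_features = max_features,
                    min_leaf = min_leaf, seed = derive_seed(seed, 200L + i)))
    pred <- predict(model, split$test)
    reports[[i]] <- evaluate_predictions(split$test$y, pred$score, pred$label)
  }
  tbl <- data.frame(fold = seq_len(k))
  for (m in eval_metric_names) tbl[[m]] <- vapply(reports, `[[`, numeric(1), m)
  structure(list(folds = reports, table = tbl,
                 summary = aggregate_metrics(tbl[eval_metric_names]),
                 config = list(k = k, smote_percent = smote_percent,
                               k_neighbors = k_neighbors, n_trees = n_trees,
                               max_features = max_features, min_leaf = min_leaf,
                               seed = seed)),
            class = "gpcr_cv")
}

#' @export
print.gpcr_cv <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf("%d-fold cross-validation (SMOTE %d%%, %d trees, seed %d)\n",
              cfg$k, cfg$smote_percent, cfg$n_trees, cfg$seed))
  tbl <- x$table
  tbl[-1] <- lapply(tbl[-1], round, digits)
  print(tbl, row.names = FALSE)
  cat("\n")
  agg <- x$summary
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-13s %.*f +/- %.*f\n", agg$metric[i],
                digits, agg$mean[i], digits, agg$sd[i]))
  }
  invisible(x)
}

#' @export
summary.gpcr_cv <- function(object, ...) object$summary

#' Plot per-fold ROC curves
#'
#' @param x a `gpcr_cv`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gpcr_cv <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate (1 - Sp)",
                 ylab = "True positive rate (Sn)",
                 main = "Per-fold ROC", ...)
  for (i in seq_along(x$folds)) {
    pts <- x$folds[[i]]$roc_points
    graphics::lines(pts$fpr, pts$tpr, col = i)
  }
  graphics::legend("bottomright", bty = "n", col = seq_along(x$folds), lty = 1,
                   legend = sprintf("fold %d (AUC %.3f)", seq_along(x$folds),
                                    vapply(x$folds, `[[`, numeric(1), "auc")))
  invisible(x)
}

#' Write a cross-validation report as a tab-separated table
#'
#' One row per fold plus `mean` and `sd` rows, mirroring the usual
#' per-fold performance table.
#'
#' @param cv a `gpcr_cv`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tbl <- cv$table
  tbl$fold <- as.character(tbl$fold)
  agg <- cv$summary
  mean_row <- c(fold = "mean", as.list(stats::setNames(agg$mean, agg$metric)))
  sd_row <- c(fold = "sd", as.list(stats::setNames(agg$sd, agg$metric)))
  out <- rbind(tbl, as.data.frame(mean_row, stringsAsFactors = FALSE),
               as.data.frame(sd_row, stringsAsFactors = FALSE))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 6, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
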