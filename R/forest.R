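# Random-Forest classification of 188D feature vectors. The ensemble itself
# is randomForest's; this layer fixes the contract the pipeline relies on:
# seeded determinism, vote-fraction scores and the score >= 0.5 => +1 rule.

#' Forest configuration
#'
#' @param n_trees number of trees (default 100).
#' @param max_features `"sqrt"` (floor of the square root of the feature
#'   count) or an integer number of candidate features per split.
#' @param seed integer seed; fits are deterministic given it.
#' @param min_leaf minimum terminal-node size (default 1, i.e. fully grown
#'   trees).
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 100, max_features = "sqrt", seed = 1, min_leaf = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (!identical(max_features, "sqrt") && (!is.numeric(max_features) || max_features < 1)) {
    stop("max_features must be \"sqrt\" or a positive integer")
  }
  if (min_leaf < 1) stop("min_leaf must be >= 1")
  structure(list(n_trees = as.integer(n_trees), max_features = max_features,
                 seed = as.integer(seed), min_leaf = as.integer(min_leaf)),
            class = "forest_config")
}

#' Fit a GPCR/non-GPCR Random-Forest classifier
#'
#' Trains a bagged decision-tree ensemble (bootstrap sample per tree,
#' `max_features` candidate features per split) on a labeled feature dataset.
#' The positive class is +1 (GPCR). Deterministic given `config$seed`.
#'
#' @param data a labeled `gpcr_dataset` containing both classes.
#' @param config a [forest_config()].
#' @return an object of class `gpcr_rf` with `predict`, `print` and `summary`
#'   methods.
#' @export
gpcr_rf <- function(data, config = forest_config()) {
  if (anyNA(data$y)) stop("training data must be fully labeled")
  if (length(unique(data$y)) < 2L) stop("training data must contain both classes")
  if (nrow(data$x) < 2L) stop("need at least 2 training samples")
  mtry <- if (identical(config$max_features, "sqrt")) {
    max(1L, floor(sqrt(ncol(data$x))))
  } else as.integer(config$max_features)
  yf <- factor(ifelse(data$y == 1L, "1", "-1"), levels = c("-1", "1"))
  forest <- with_seed(config$seed,
    randomForest::randomForest(x = data$x, y = yf, ntree = config$n_trees,
                               mtry = mtry, nodesize = config$min_leaf))
  structure(list(forest = forest, config = config, n_features = ncol(data$x),
                 feature_names = colnames(data$x),
                 n_train = c(pos = sum(data$y == 1L), neg = sum(data$y == -1L))),
            class = "gpcr_rf")
}

#' Predict GPCR membership
#'
#' The score of a vector is the fraction of trees voting for the positive
#' class; the predicted label is +1 iff score >= 0.5 (ties go to +1).
#'
#' @param object a fitted `gpcr_rf`.
#' @param newdata a `gpcr_dataset` or numeric matrix with the training
#'   feature columns.
#' @param ... unused.
#' @return a `data.frame` with columns `id`, `score`, `label`, in input order.
#' @export
predict.gpcr_rf <- function(object, newdata, ...) {
  if (inherits(newdata, "gpcr_dataset")) {
    ids <- newdata$ids
    x <- newdata$x
  } else {
    x <- as.matrix(newdata)
    ids <- if (!is.null(rownames(x))) rownames(x) else paste0("v", seq_len(nrow(x)))
  }
  if (ncol(x) != object$n_features) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 object$n_features, ncol(x)))
  }
  colnames(x) <- object$feature_names
  score <- unname(stats::predict(object$forest, x, type = "prob")[, "1"])
  data.frame(id = ids, score = score,
             label = ifelse(score >= 0.5, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' @export
print.gpcr_rf <- function(x, ...) {
  cat(sprintf("<gpcr_rf> %d trees, mtry %s, trained on %d positives / %d negatives (%d features)\n",
              x$config$n_trees,
              if (identical(x$config$max_features, "sqrt"))
                sprintf("sqrt (%d)", max(1L, floor(sqrt(x$n_features))))
              else x$config$max_features,
              x$n_train["pos"], x$n_train["neg"], x$n_features))
  invisible(x)
}

#' @export
summary.gpcr_rf <- function(object, ...) {
  print(object)
  cat("Out-of-bag confusion (training data):\n")
  print(object$forest$confusion)
  invisible(object)
}

#' Save / load a fitted model
#'
#' Single-file persistence of the fitted ensemble together with its
#' configuration and feature contract.
#'
#' @param model a `gpcr_rf`.
#' @param path file path.
#' @return `path` (`save_model`) or the restored `gpcr_rf` (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gpcr_rf"))
  saveRDS(list(format = "gpcr188-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "gpcr188-model")) {
    stop(sprintf("not a gpcr188 model file: %s", path))
  }
  obj$model
}
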