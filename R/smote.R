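# SMOTE: synthetic minority oversampling by interpolation between a minority
# point and one of its k nearest minority neighbors. Written in-package; the
# neighbor search is exact brute force, adequate at the few-thousand-sample
# scale this pipeline runs at.

#' SMOTE configuration
#'
#' @param percent oversampling amount as a non-negative multiple of 100;
#'   `percent/100` synthetic vectors are generated per minority original.
#'   The pipeline default 300 quadruples the minority class.
#' @param k_neighbors neighborhood size for interpolation partners (default 5).
#' @param seed integer seed.
#' @return a `smote_config` list.
#' @export
smote_config <- function(percent = 300, k_neighbors = 5, seed = 1) {
  if (percent < 0 || percent %% 100 != 0) stop("percent must be a non-negative multiple of 100")
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(percent = as.integer(percent),
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' Generate synthetic minority vectors (SMOTE)
#'
#' For each minority vector x, `percent/100` synthetic vectors are generated
#' as `x + u * (x_nn - x)` with `u ~ Uniform(0,1)` and `x_nn` one of x's
#' `k_neighbors` nearest minority neighbors (Euclidean distance, ties broken
#' by lower input index). Output order is deterministic given the seed:
#' originals in input order, `percent/100` synthetics each. Only the synthetic
#' vectors are returned.
#'
#' @param minority a `gpcr_dataset` (or numeric matrix) holding minority-class
#'   vectors only; all labels must agree.
#' @param config a [smote_config()].
#' @return a `gpcr_dataset` of synthetic vectors carrying the minority label
#'   and ids of the form `syn<j>_<parent id>`.
#' @export
smote <- function(minority, config = smote_config()) {
  if (is.matrix(minority)) minority <- feature_dataset(minority, rep(1L, nrow(minority)))
  x <- minority$x
  lab <- unique(minority$y)
  if (length(lab) != 1L) stop("minority vectors must share one label")
  g <- config$percent %/% 100L
  if (g == 0L) {
    return(feature_dataset(x[0, , drop = FALSE], integer(0), character(0)))
  }
  n <- nrow(x)
  if (n <= config$k_neighbors) {
    stop(sprintf("need more than k_neighbors = %d minority samples (got %d)",
                 config$k_neighbors, n))
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # order() is stable, so equal distances resolve to the lower input index
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(config$k_neighbors)]))
  syn <- matrix(NA_real_, n * g, ncol(x), dimnames = list(NULL, colnames(x)))
  ids <- character(n * g)
  with_seed(config$seed, {
    row <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(g)) {
        row <- row + 1L
        partner <- nn[i, sample.int(config$k_neighbors, 1L)]
        u <- stats::runif(1)
        syn[row, ] <- x[i, ] + u * (x[partner, ] - x[i, ])
        ids[row] <- sprintf("syn%d_%s", j, minority$ids[i])
      }
    }
  })
  feature_dataset(syn, rep(lab, n * g), ids)
}

#' Rebalance a fold's training set with SMOTE
#'
#' Appends synthetic minority vectors to the training partition; the test
#' partition is returned untouched — synthetic data never enters a test set.
#' The minority class is the less frequent training label.
#'
#' @param split one fold split from [make_folds()].
#' @param config a [smote_config()].
#' @return the split with an augmented training set.
#' @export
rebalance_training <- function(split, config = smote_config()) {
  y <- split$train$y
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  if (config$percent == 0L) return(split)
  minority_label <- if (sum(y == 1L) <= sum(y == -1L)) 1L else -1L
  syn <- smote(subset_dataset(split$train, which(y == minority_label)), config)
  split$train <- combine_datasets(split$train, syn)
  split
}
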