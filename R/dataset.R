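# Labeled feature datasets, stratified k-fold splits, ARFF input/output and
# the greedy k-mer redundancy filter.

#' Construct a labeled feature dataset
#'
#' The container used throughout the pipeline: a numeric feature matrix
#' (rows = sequences), an optional label vector over \{+1, -1\} (NA =
#' unlabeled) and row ids.
#'
#' @param x numeric matrix, one row per vector.
#' @param y integer labels, `+1`/`-1`/`NA`, length `nrow(x)`; default all NA.
#' @param ids row identifiers; defaults to rownames of `x` or `v1..vn`.
#' @return an object of class `gpcr_dataset`.
#' @export
feature_dataset <- function(x, y = NULL, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(y)) y <- rep(NA_integer_, n)
  y <- as.integer(y)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (!all(y %in% c(-1L, 1L) | is.na(y))) stop("labels must be +1, -1 or NA")
  if (is.null(ids)) ids <- if (!is.null(rownames(x))) rownames(x) else paste0("v", seq_len(n))
  if (length(ids) != n) stop("length(ids) must equal nrow(x)")
  rownames(x) <- NULL
  structure(list(x = x, y = y, ids = as.character(ids)), class = "gpcr_dataset")
}

#' @export
print.gpcr_dataset <- function(x, ...) {
  cat(sprintf("<gpcr_dataset> %d vectors x %d features; +1: %d, -1: %d, unlabeled: %d\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L, na.rm = TRUE),
              sum(x$y == -1L, na.rm = TRUE), sum(is.na(x$y))))
  invisible(x)
}

#' Row-subset a dataset
#' @param data a `gpcr_dataset`.
#' @param idx integer row indices.
#' @return a `gpcr_dataset`.
#' @export
subset_dataset <- function(data, idx) {
  feature_dataset(data$x[idx, , drop = FALSE], data$y[idx], data$ids[idx])
}

#' Concatenate datasets row-wise
#' @param ... `gpcr_dataset` objects with identical feature columns.
#' @return a `gpcr_dataset`.
#' @export
combine_datasets <- function(...) {
  parts <- list(...)
  cn <- colnames(parts[[1]]$x)
  for (p in parts[-1]) {
    if (!identical(colnames(p$x), cn)) stop("datasets have different feature columns")
  }
  feature_dataset(do.call(rbind, lapply(parts, `[[`, "x")),
                  unlist(lapply(parts, `[[`, "y")),
                  unlist(lapply(parts, `[[`, "ids")))
}

# part sizes for a stratified split: floor(n/k) each, remainder r assigned to
# the last r parts (so only the highest-indexed folds carry the extra sample)
part_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0L) sizes[(k - r + 1L):k] <- sizes[(k - r + 1L):k] + 1L
  sizes
}

#' Stratified k-fold split
#'
#' Positives and negatives are shuffled independently (seeded) and each split
#' into k near-equal parts: every part gets `floor(n/k)` members and the
#' remainder goes to the highest-indexed parts. Fold i's test set is part i of
#' each class; its training set is everything else. Deterministic given
#' `seed`.
#'
#' @param data a labeled `gpcr_dataset` (no NA labels).
#' @param k number of folds (>= 2).
#' @param seed integer seed for the two shuffles.
#' @return a list of k fold splits, each
#'   `list(fold, train, test, test_idx)` with `train`/`test` datasets.
#' @export
make_folds <- function(data, k = 5, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (anyNA(data$y)) stop("make_folds requires a fully labeled dataset")
  pos <- which(data$y == 1L)
  neg <- which(data$y == -1L)
  if (length(pos) < k || length(neg) < k) {
    stop(sprintf("each class needs at least k = %d members (got %d positives, %d negatives)",
                 k, length(pos), length(neg)))
  }
  with_seed(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
  })
  fold_of <- function(n) factor(rep(seq_len(k), part_sizes(n, k)), levels = seq_len(k))
  pos_parts <- split(pos, fold_of(length(pos)))
  neg_parts <- split(neg, fold_of(length(neg)))
  lapply(seq_len(k), function(i) {
    test_idx <- sort(c(pos_parts[[i]], neg_parts[[i]]))
    train_idx <- setdiff(seq_along(data$y), test_idx)
    list(fold = i,
         train = subset_dataset(data, train_idx),
         test = subset_dataset(data, test_idx),
         test_idx = test_idx)
  })
}

#' Write a labeled dataset to ARFF
#'
#' Produces a standard ARFF file: a relation line, one numeric attribute per
#' feature, a nominal class attribute with values \{1, -1\} and one data row
#' per vector with the label last. Feature values are written with 6
#' significant digits. [read_arff()] inverts it.
#'
#' @param data a labeled `gpcr_dataset`.
#' @param path output path.
#' @param relation relation name for the header line.
#' @return `path`, invisibly.
#' @export
write_arff <- function(data, path, relation = "gpcr188") {
  if (nrow(data$x) == 0L) stop("empty dataset")
  if (anyNA(data$y)) stop("ARFF export requires labels on every vector")
  df <- as.data.frame(signif(data$x, 6))
  names(df) <- colnames(data$x)
  df$class <- factor(ifelse(data$y == 1L, "1", "-1"), levels = c("1", "-1"))
  foreign::write.arff(df, path)
  # foreign derives the relation name from the data-frame variable; rewrite it
  lines <- readLines(path, warn = FALSE)
  lines[1] <- paste("@relation", relation)
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled dataset from ARFF
#'
#' Expects numeric feature attributes followed by a final nominal class
#' attribute over \{1, -1\} (as written by [write_arff()] or Weka).
#'
#' @param path path to an ARFF file.
#' @return a `gpcr_dataset`, vectors in file order.
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) stop(sprintf("ARFF file not found: %s", path))
  df <- foreign::read.arff(path)
  if (ncol(df) < 2L) stop("ARFF must have at least one feature attribute plus a class attribute")
  cls <- df[[ncol(df)]]
  feats <- df[-ncol(df)]
  nonnum <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop(sprintf("non-numeric feature attribute(s): %s", paste(nonnum, collapse = ", ")))
  }
  cls <- as.character(cls)
  bad <- setdiff(unique(cls), c("1", "-1"))
  if (length(bad)) {
    stop(sprintf("unknown class value(s): %s (expected 1 or -1)",
                 paste(sQuote(bad), collapse = ", ")))
  }
  feature_dataset(as.matrix(feats), ifelse(cls == "1", 1L, -1L))
}

#' Export a dataset as a tab-separated table
#'
#' Columns: id, the feature values, label (empty when unlabeled).
#'
#' @param data a `gpcr_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(data, path) {
  df <- data.frame(id = data$ids, data$x, label = data$y,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

distinct_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1), k:L))
}

#' Greedy k-mer redundancy filter
#'
#' A lightweight, alignment-free stand-in for identity-threshold clustering
#' (CD-HIT style): records are processed in order of decreasing length; each
#' joins the first retained representative whose estimated identity — the
#' fraction of the shorter sequence's distinct k-mers found in the longer
#' sequence — reaches `identity_threshold`, otherwise it becomes a new
#' representative. Deterministic; an estimator, not an aligner.
#'
#' @param records a record `data.frame`.
#' @param identity_threshold fraction in (0, 1], e.g. 0.8.
#' @param k k-mer length (default 5).
#' @return the representative records, in processing order.
#' @export
greedy_redundancy_filter <- function(records, identity_threshold = 0.8, k = 5) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  if (nrow(records) == 0L) return(records)
  ord <- order(-nchar(records$sequence), seq_len(nrow(records)))
  recs <- records[ord, , drop = FALSE]
  reps <- integer(0)
  rep_kmers <- list()
  for (i in seq_len(nrow(recs))) {
    km <- distinct_kmers(recs$sequence[i], k)
    matched <- FALSE
    for (r in seq_along(reps)) {
      ident <- if (length(km) == 0L) {
        as.numeric(identical(recs$sequence[i], recs$sequence[reps[r]]))
      } else {
        # processing order guarantees the representative is the longer one
        mean(km %in% rep_kmers[[r]])
      }
      if (ident >= identity_threshold) { matched <- TRUE; break }
    }
    if (!matched) {
      reps <- c(reps, i)
      rep_kmers[[length(reps)]] <- km
    }
  }
  out <- recs[reps, , drop = FALSE]
  rownames(out) <- NULL
  out
}
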