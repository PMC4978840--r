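# The 188D feature encoding: 20 amino-acid composition values plus, per
# property, 3 composition + 3 transition + 15 distribution values.

#' Amino-acid composition
#'
#' Frequency of each of the 20 standard residues, alphabetical by one-letter
#' code (the order of [AA20]). Values sum to 1.
#'
#' @param sequence a non-empty sequence over the 20 standard codes.
#' @return named numeric vector of length 20.
#' @export
aac <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (length(idx) == 0L) stop("empty sequence")
  if (anyNA(idx)) stop("sequence contains residues outside the 20-letter alphabet")
  stats::setNames(tabulate(idx, 20L) / length(idx), AA20)
}

cls_ints <- function(cls) {
  v <- as.integer(strsplit(cls, "")[[1]])
  if (length(v) == 0L) stop("empty class string")
  if (anyNA(v) || any(v < 1L | v > 3L)) stop("class string must be over {1,2,3}")
  v
}

#' CTD composition: class fractions
#'
#' @param cls a class string over \{1,2,3\} ([class_string()]).
#' @return numeric vector `c(C1, C2, C3)`; sums to 1.
#' @export
ctd_composition <- function(cls) {
  v <- cls_ints(cls)
  tabulate(v, 3L) / length(v)
}

#' CTD transition: adjacent cross-class pair frequencies
#'
#' `T_jk` is the number of adjacent positions holding classes j and k in
#' either order, divided by L-1. Order of the result: T12, T13, T23. A
#' length-1 string returns `c(0, 0, 0)` so degenerate sequences survive batch
#' encoding.
#'
#' @inheritParams ctd_composition
#' @return numeric vector `c(T12, T13, T23)`, each in \[0, 1\].
#' @export
ctd_transition <- function(cls) {
  v <- cls_ints(cls)
  L <- length(v)
  if (L < 2L) return(c(0, 0, 0))
  a <- v[-L]; b <- v[-1]
  lo <- pmin(a, b); hi <- pmax(a, b)
  c(sum(lo == 1L & hi == 2L), sum(lo == 1L & hi == 3L), sum(lo == 2L & hi == 3L)) / (L - 1)
}

#' CTD distribution: positional anchors of each class
#'
#' For class j occurring n times at positions p_1 < ... < p_n, the five values
#' are 100 * p_m / L at the first occurrence and at the occurrences where 25%,
#' 50%, 75% and 100% of the class's residues have been seen; the occurrence
#' index for quantile q is `max(1, ceiling(q * n))`. An absent class yields
#' five zeros.
#'
#' @inheritParams ctd_composition
#' @return numeric vector of 15 values (five per class), in \[0, 100\].
#' @export
ctd_distribution <- function(cls) {
  v <- cls_ints(cls)
  L <- length(v)
  out <- numeric(15)
  for (j in 1:3) {
    pos <- which(v == j)
    n <- length(pos)
    if (n > 0L) {
      m <- c(1L, pmax(1L, ceiling(c(0.25, 0.50, 0.75, 1.00) * n)))
      out[(j - 1L) * 5L + 1:5] <- 100 * pos[m] / L
    }
  }
  out
}

#' Names of the 188 features, in vector order
#'
#' @param groupings a list of 8 `aa_grouping`s (default [default_groupings()]).
#' @return character vector of length 188.
#' @export
feature_names <- function(groupings = default_groupings()) {
  stopifnot(length(groupings) == 8L)
  per_prop <- c("C1", "C2", "C3", "T12", "T13", "T23",
                paste0("D", rep(1:3, each = 5), ".",
                       rep(c("first", "q25", "q50", "q75", "q100"), 3)))
  c(paste0("aac.", AA20),
    unlist(lapply(groupings, function(g) paste0(g$name, ".", per_prop)),
           use.names = FALSE))
}

#' Encode one sequence as a 188D feature vector
#'
#' Layout: positions 1-20 are the amino-acid composition ([aac()]); then one
#' 21-value block per property grouping, in grouping order, laid out
#' C1,C2,C3,T12,T13,T23 followed by the five distribution values of class 1,
#' class 2 and class 3.
#'
#' @param sequence a non-empty sequence over the 20 standard codes.
#' @param groupings a list of exactly 8 `aa_grouping`s.
#' @return named numeric vector of length 188.
#' @export
encode_188 <- function(sequence, groupings = default_groupings()) {
  if (length(groupings) != 8L) stop("exactly 8 property groupings are required")
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (length(idx) == 0L) stop("empty sequence")
  if (anyNA(idx)) stop("sequence contains residues outside the 20-letter alphabet")
  L <- length(idx)
  blocks <- vector("list", 9L)
  blocks[[1]] <- tabulate(idx, 20L) / L
  for (p in seq_along(groupings)) {
    v <- grouping_lut(groupings[[p]])[idx]
    cls <- paste(v, collapse = "")
    blocks[[p + 1L]] <- c(ctd_composition(cls), ctd_transition(cls), ctd_distribution(cls))
  }
  stats::setNames(unlist(blocks, use.names = FALSE), feature_names(groupings))
}

#' Encode many records into a labeled feature dataset
#'
#' Order-preserving; every row carries the supplied label and its source id.
#' An encoding failure aborts with the offending record's id named.
#'
#' @param records a record `data.frame` ([protein_records()] / [read_fasta()]).
#' @param groupings a list of 8 `aa_grouping`s.
#' @param label `+1` (GPCR), `-1` (non-GPCR) or `NA` for unlabeled.
#' @return a [feature_dataset()].
#' @export
encode_many <- function(records, groupings = default_groupings(), label = NA) {
  if (nrow(records) == 0L) stop("no records to encode")
  x <- matrix(NA_real_, nrow(records), 188L,
              dimnames = list(records$id, feature_names(groupings)))
  for (i in seq_len(nrow(records))) {
    x[i, ] <- tryCatch(encode_188(records$sequence[i], groupings),
                       error = function(e) {
                         stop(sprintf("encoding record '%s' failed: %s",
                                      records$id[i], conditionMessage(e)))
                       })
  }
  feature_dataset(x, y = rep(if (is.na(label)) NA_integer_ else as.integer(label),
                             nrow(records)),
                  ids = records$id)
}
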