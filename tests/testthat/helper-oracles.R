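# Independent brute-force oracles, deliberately implemented by a different
# route than the package code they check.

# Transition frequencies by tabulating every adjacent ordered pair.
oracle_transition <- function(cls) {
  L <- nchar(cls)
  if (L < 2) return(c(0, 0, 0))
  pairs <- paste0(substring(cls, 1:(L - 1), 1:(L - 1)),
                  substring(cls, 2:L, 2:L))
  cnt <- function(p) sum(pairs == p)
  c(cnt("12") + cnt("21"), cnt("13") + cnt("31"), cnt("23") + cnt("32")) / (L - 1)
}

# Distribution anchors by scanning the string and recording where the running
# count of each class first reaches the required fraction of its total.
oracle_distribution <- function(cls) {
  ch <- strsplit(cls, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (j in c("1", "2", "3")) {
    n <- sum(ch == j)
    if (n == 0) { out <- c(out, rep(0, 5)); next }
    needed <- c(1, sapply(c(0.25, 0.5, 0.75, 1), function(q) max(1, ceiling(q * n))))
    anchors <- numeric(5)
    for (a in seq_along(needed)) {
      count <- 0
      for (p in seq_len(L)) {
        if (ch[p] == j) count <- count + 1
        if (count == needed[a]) { anchors[a] <- 100 * p / L; break }
      }
    }
    out <- c(out, anchors)
  }
  out
}

# AUC by exhaustive positive-negative pair comparison, ties worth 1/2.
oracle_auc <- function(truth, scores) {
  ps <- scores[truth == 1]
  ns <- scores[truth == -1]
  wins <- 0
  for (p in ps) for (n in ns) wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(ps) * length(ns))
}

# All class strings of a given length over {1,2,3}.
all_class_strings <- function(len) {
  apply(expand.grid(rep(list(c("1", "2", "3")), len)), 1, paste, collapse = "")
}

random_sequence <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

make_records <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  protein_records(id = ids, sequence = seqs)
}

# A trivially separable labeled dataset: positives high in feature 1.
separable_dataset <- function(n_per_class = 10, dim = 5, seed = 42) {
  withr::with_seed(seed, {
    pos <- matrix(runif(n_per_class * dim), n_per_class, dim)
    neg <- matrix(runif(n_per_class * dim), n_per_class, dim)
    pos[, 1] <- pos[, 1] + 5
    x <- rbind(pos, neg)
    colnames(x) <- paste0("f", seq_len(dim))
    feature_dataset(x, c(rep(1L, n_per_class), rep(-1L, n_per_class)))
  })
}
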