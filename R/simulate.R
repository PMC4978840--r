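# Seeded generator of synthetic sequence populations: "receptor-like"
# sequences with seven hydrophobic-enriched stretches separated by loops of
# globular composition, and background sequences drawn from Swiss-Prot-like
# residue frequencies. Compositional mimicry only — no real topology or
# motifs — but enough class separation to exercise the whole pipeline.

# Approximate Swiss-Prot residue frequencies (globular background), AA20 order
BACKGROUND_FREQS <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)

HYDROPHOBIC7 <- c("C", "L", "V", "I", "M", "F", "W")
MIN_LOOP <- 3L

#' Synthetic-sequence generator configuration
#'
#' @param n_pos,n_neg number of receptor-like and background sequences.
#'   Default 100 / 400: a 1:4 imbalance matching the GPCR:non-GPCR ratio the
#'   classifier is meant to face.
#' @param length_range total sequence length range (default 250-420 residues,
#'   room for seven 18-25-residue membrane-like stretches plus loops).
#' @param n_helices number of hydrophobic stretches per positive (default 7).
#' @param helix_length_range length range of each stretch (default 18-25).
#' @param hydrophobic_bias probability mass placed on \{C,L,V,I,M,F,W\} inside
#'   a stretch (default 0.8).
#' @param seed integer seed; generation is deterministic given it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_pos = 100, n_neg = 400, length_range = c(250, 420),
                             n_helices = 7, helix_length_range = c(18, 25),
                             hydrophobic_bias = 0.8, seed = 1) {
  if (n_pos < 1 || n_neg < 1) stop("n_pos and n_neg must be positive")
  if (length_range[1] > length_range[2] || helix_length_range[1] > helix_length_range[2]) {
    stop("range minima must not exceed maxima")
  }
  if (hydrophobic_bias <= 0 || hydrophobic_bias >= 1) stop("hydrophobic_bias must be in (0, 1)")
  worst <- n_helices * helix_length_range[2] + (n_helices - 1) * MIN_LOOP
  if (worst > length_range[2]) {
    stop(sprintf("infeasible lengths: %d helices of up to %d residues need %d, max length is %d",
                 n_helices, helix_length_range[2], worst, length_range[2]))
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 n_helices = as.integer(n_helices),
                 helix_length_range = as.integer(helix_length_range),
                 hydrophobic_bias = hydrophobic_bias, seed = as.integer(seed)),
            class = "generator_config")
}

sample_background <- function(n) {
  sample(AA20, n, replace = TRUE, prob = BACKGROUND_FREQS)
}

one_positive <- function(cfg) {
  h_len <- sample(cfg$helix_length_range[1]:cfg$helix_length_range[2],
                  cfg$n_helices, replace = TRUE)
  L <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
  L <- max(L, sum(h_len) + (cfg$n_helices - 1L) * MIN_LOOP)
  n_loops <- cfg$n_helices + 1L
  loop_len <- integer(n_loops)
  loop_len[2:cfg$n_helices] <- MIN_LOOP  # interior loops always separate helices
  spare <- L - sum(h_len) - sum(loop_len)
  if (spare > 0L) {
    extra <- tabulate(sample.int(n_loops, spare, replace = TRUE), n_loops)
    loop_len <- loop_len + extra
  }
  parts <- character(2L * cfg$n_helices + 1L)
  for (i in seq_len(cfg$n_helices)) {
    parts[2L * i - 1L] <- paste(sample_background(loop_len[i]), collapse = "")
    hydro <- stats::runif(h_len[i]) < cfg$hydrophobic_bias
    res <- character(h_len[i])
    res[hydro] <- sample(HYDROPHOBIC7, sum(hydro), replace = TRUE)
    res[!hydro] <- sample(setdiff(AA20, HYDROPHOBIC7), sum(!hydro), replace = TRUE)
    parts[2L * i] <- paste(res, collapse = "")
  }
  parts[2L * cfg$n_helices + 1L] <- paste(sample_background(loop_len[n_loops]), collapse = "")
  paste(parts, collapse = "")
}

#' Generate synthetic receptor-like sequences
#'
#' Each sequence alternates `n_helices` hydrophobic-biased stretches with
#' loops drawn from globular background frequencies.
#'
#' @param config a [generator_config()].
#' @return a record `data.frame` of `n_pos` sequences.
#' @export
generate_positive <- function(config = generator_config()) {
  seqs <- with_seed(config$seed,
                    vapply(seq_len(config$n_pos), function(i) one_positive(config),
                           character(1)))
  protein_records(id = sprintf("pos%04d", seq_len(config$n_pos)),
                  sequence = seqs,
                  description = "synthetic receptor-like")
}

#' Generate synthetic background sequences
#'
#' Sequences drawn residue-by-residue from Swiss-Prot-like globular
#' frequencies, lengths uniform over `length_range`.
#'
#' @param config a [generator_config()].
#' @return a record `data.frame` of `n_neg` sequences.
#' @export
generate_negative <- function(config = generator_config()) {
  seqs <- with_seed(derive_seed(config$seed, 7L), {
    vapply(seq_len(config$n_neg), function(i) {
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      paste(sample_background(L), collapse = "")
    }, character(1))
  })
  protein_records(id = sprintf("neg%04d", seq_len(config$n_neg)),
                  sequence = seqs,
                  description = "synthetic background")
}
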