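test_that("amino-acid composition matches hand tallies and sums to 1", {
  expect_equal(unname(aac("AAAA")), c(1, rep(0, 19)))
  v <- aac("ACDE")
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(v), 1)
  # hand-tallied: A 2, K 2, I/M/Q/R/T/Y 1 each, over 10 residues
  v <- aac("MKTAYIAKQR")
  expect_equal(v[["A"]], 0.2)
  expect_equal(v[["K"]], 0.2)
  expect_equal(unname(v[c("I", "M", "Q", "R", "T", "Y")]), rep(0.1, 6))
  expect_equal(sum(v), 1)
  expect_error(aac(""), "empty")
})

test_that("CTD composition is the per-class fraction", {
  expect_equal(ctd_composition("1111"), c(1, 0, 0))
  expect_equal(ctd_composition("123123"), rep(1 / 3, 3))
  expect_equal(ctd_composition("1133"), c(0.5, 0, 0.5))
})

test_that("CTD transition counts unordered adjacent cross-class pairs", {
  expect_equal(ctd_transition("1111"), c(0, 0, 0))
  expect_equal(ctd_transition("12"), c(1, 0, 0))
  # pairs of "121332": 12, 21, 13, 33, 32
  expect_equal(ctd_transition("121332"), c(2 / 5, 1 / 5, 1 / 5))
  expect_equal(ctd_transition("1"), c(0, 0, 0))
})

test_that("CTD distribution anchors match the ceiling rule", {
  expect_equal(ctd_distribution("1111"), c(25, 25, 50, 75, 100, rep(0, 10)))
  expect_equal(ctd_distribution("2222222222")[6:10], c(10, 30, 50, 80, 100))
  expect_equal(ctd_distribution("12")[11:15], rep(0, 5))
})

test_that("transition and distribution match brute-force oracles exhaustively", {
  for (len in 1:6) {
    for (cls in all_class_strings(len)) {
      expect_equal(ctd_transition(cls), oracle_transition(cls))
      expect_equal(ctd_distribution(cls), oracle_distribution(cls))
    }
  }
})

test_that("encode_188 produces the fixed 188-position layout", {
  v <- encode_188("MKTAYIAKQR")
  expect_length(v, 188L)
  expect_equal(names(v), feature_names())
  # assembled from independently computed sub-blocks
  g <- default_groupings()
  expect_equal(unname(v[1:20]), unname(aac("MKTAYIAKQR")))
  for (p in seq_along(g)) {
    cls <- class_string("MKTAYIAKQR", g[[p]])
    block <- 20L + (p - 1L) * 21L
    expect_equal(unname(v[block + 1:3]), ctd_composition(cls))
    expect_equal(unname(v[block + 4:6]), ctd_transition(cls))
    expect_equal(unname(v[block + 7:21]), ctd_distribution(cls))
  }
})

test_that("poly-A encodes as pure composition with no transitions", {
  v <- encode_188(paste(rep("A", 30), collapse = ""))
  expect_equal(v[["aac.A"]], 1)
  expect_true(all(v[grep("\\.T(12|13|23)$", names(v))] == 0))
  # each property block has exactly one nonzero distribution class (A's class)
  for (g in default_groupings()) {
    d <- v[grep(paste0("^", g$name, "\\.D"), names(v))]
    expect_equal(sum(matrix(d, nrow = 5) != 0) %/% 5, 1L)
  }
})

test_that("value ranges and normalisation hold for random sequences", {
  withr::with_seed(21, {
    for (i in 1:25) {
      s <- random_sequence(sample(1:200, 1))
      v <- encode_188(s)
      expect_length(v, 188L)
      expect_true(all(is.finite(v)))
      expect_equal(sum(v[1:20]), 1)
      for (p in 1:8) {
        block <- 20L + (p - 1L) * 21L
        expect_equal(sum(v[block + 1:3]), 1)
        expect_true(all(v[block + 4:6] >= 0 & v[block + 4:6] <= 1))
        expect_true(sum(v[block + 4:6]) <= 1 + 1e-12)
        expect_true(all(v[block + 7:21] >= 0 & v[block + 7:21] <= 100))
      }
    }
  })
})

test_that("composition blocks are permutation-invariant; output is deterministic", {
  withr::with_seed(33, {
    s <- strsplit(random_sequence(60), "")[[1]]
    v1 <- encode_188(paste(s, collapse = ""))
    v2 <- encode_188(paste(sample(s), collapse = ""))
  })
  comp_idx <- c(1:20, unlist(lapply(0:7, function(p) 20L + p * 21L + 1:3)))
  expect_equal(v1[comp_idx], v2[comp_idx])
  expect_identical(encode_188(paste(s, collapse = "")), v1)
})

test_that("encode_many preserves order, labels and ids, and names failures", {
  recs <- make_records(c("MKT", "ACDE", "WWWW"))
  ds <- encode_many(recs, label = 1)
  expect_equal(ds$ids, recs$id)
  expect_equal(ds$y, rep(1L, 3))
  expect_equal(unname(ds$x[2, ]), unname(encode_188("ACDE")))
  unl <- encode_many(recs)
  expect_true(all(is.na(unl$y)))
  bad <- recs
  bad$sequence[2] <- "AXC"  # bypasses the constructor's validation
  expect_error(encode_many(bad), "s2")
})
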