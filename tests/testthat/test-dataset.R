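dummy_dataset <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  feature_dataset(matrix(seq_len(n), ncol = 1),
                  c(rep(1L, n_pos), rep(-1L, n_neg)))
}

test_that("stratified folds carry near-equal class counts, remainder to the last folds", {
  folds <- make_folds(dummy_dataset(13, 22), k = 5, seed = 3)
  test_pos <- vapply(folds, function(f) sum(f$test$y == 1L), integer(1))
  test_neg <- vapply(folds, function(f) sum(f$test$y == -1L), integer(1))
  expect_equal(test_pos, c(2L, 2L, 3L, 3L, 3L))
  expect_equal(test_neg, c(4L, 4L, 4L, 5L, 5L))
})

test_that("each fold partitions the data and test sets tile it exactly", {
  ds <- dummy_dataset(11, 31)
  folds <- make_folds(ds, k = 5, seed = 8)
  all_test <- unlist(lapply(folds, `[[`, "test_idx"))
  expect_equal(sort(all_test), seq_along(ds$y))       # no duplicates, full cover
  for (f in folds) {
    expect_length(intersect(f$test_idx, setdiff(seq_along(ds$y), f$test_idx)), 0L)
    expect_equal(nrow(f$train$x) + nrow(f$test$x), length(ds$y))
    expect_true(all(c(-1L, 1L) %in% f$test$y))        # stratification
  }
})

test_that("tiny balanced input yields one member of each class per test fold", {
  folds <- make_folds(dummy_dataset(5, 5), k = 5, seed = 1)
  for (f in folds) {
    expect_equal(sum(f$test$y == 1L), 1L)
    expect_equal(sum(f$test$y == -1L), 1L)
  }
})

test_that("folds are deterministic in the seed and change with it", {
  ds <- dummy_dataset(20, 40)
  f1 <- make_folds(ds, k = 5, seed = 7)
  f2 <- make_folds(ds, k = 5, seed = 7)
  f3 <- make_folds(ds, k = 5, seed = 8)
  expect_identical(lapply(f1, `[[`, "test_idx"), lapply(f2, `[[`, "test_idx"))
  expect_false(identical(lapply(f1, `[[`, "test_idx"), lapply(f3, `[[`, "test_idx")))
})

test_that("classes smaller than k are rejected", {
  expect_error(make_folds(dummy_dataset(3, 10), k = 5), "at least k")
})

test_that("ARFF files round-trip values (6 significant digits) and labels", {
  withr::with_seed(14, {
    ds <- encode_many(make_records(replicate(4, random_sequence(50))), label = 1)
    neg <- encode_many(make_records(replicate(3, random_sequence(50)),
                                    ids = paste0("n", 1:3)), label = -1)
  })
  both <- combine_datasets(ds, neg)
  f <- withr::local_tempfile(fileext = ".arff")
  write_arff(both, f, relation = "roundtrip")
  lines <- readLines(f)
  expect_equal(lines[1], "@relation roundtrip")
  expect_equal(sum(grepl("^@attribute", lines)), 189L)
  expect_equal(sum(grepl("^@attribute .* numeric$", lines)), 188L)
  back <- read_arff(f)
  expect_equal(back$y, both$y)
  expect_equal(back$x, both$x, tolerance = 1e-5)
  expect_equal(colnames(back$x), colnames(both$x))
})

test_that("read_arff rejects unknown class values, naming them", {
  f <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation bad", "@attribute f1 numeric", "@attribute class {1,-1,2}",
               "@data", "0.5,2"), f)
  expect_error(read_arff(f), "'2'")
})

test_that("greedy redundancy filter collapses near-identical sequences only", {
  withr::with_seed(19, {
    a <- random_sequence(100)
    mutated <- a
    substr(mutated, 50, 50) <- setdiff(AA20, substr(a, 50, 50))[1]
    b <- random_sequence(100)
  })
  recs <- make_records(c(a, a), ids = c("a", "a2"))
  expect_equal(nrow(greedy_redundancy_filter(recs, 0.8)), 1L)

  # one point mutation in 100 residues destroys at most 5 of 96 5-mers
  recs2 <- make_records(c(a, mutated), ids = c("a", "mut"))
  expect_equal(nrow(greedy_redundancy_filter(recs2, 0.8)), 1L)

  recs3 <- make_records(c(a, b), ids = c("a", "b"))
  shared <- intersect(gpcr188:::distinct_kmers(a, 5), gpcr188:::distinct_kmers(b, 5))
  expect_lt(length(shared) / 96, 0.8)   # unrelated randoms share almost nothing
  expect_equal(nrow(greedy_redundancy_filter(recs3, 0.8)), 2L)
})

test_that("feature TSV export carries ids, values and labels", {
  ds <- encode_many(make_records(c("MKT", "ACDE")), label = -1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(ds, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_equal(ncol(tab), 190L)  # id + 188 + label
  expect_equal(tab$label, c(-1L, -1L))
  expect_equal(tab$id, c("s1", "s2"))
})
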