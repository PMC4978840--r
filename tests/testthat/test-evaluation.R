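test_that("confusion counts follow the positive-class definitions", {
  cm <- confusion(c(1, 1, -1, -1), c(1, -1, -1, 1))
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion(c(1, -1, 1), c(1, -1, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  allpos <- confusion(c(1, -1), c(1, 1))
  expect_equal(unclass(allpos)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 0L, fn = 0L))
  expect_error(confusion(c(1, 1), c(1)), "lengths differ")
  expect_error(confusion(c(1, 0), c(1, 1)), "labels")
})

test_that("metrics reproduce hand-computed values", {
  m <- classification_metrics(list(tp = 1, fn = 1, tn = 1, fp = 1))
  expect_equal(unlist(m[c("sn", "sp", "acc_weighted", "acc_balanced", "mcc")]),
               c(sn = 0.5, sp = 0.5, acc_weighted = 0.5, acc_balanced = 0.5, mcc = 0))
  p <- classification_metrics(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(unlist(p[c("sn", "sp", "acc_weighted", "acc_balanced", "mcc")]),
               c(sn = 1, sp = 1, acc_weighted = 1, acc_balanced = 1, mcc = 1))
})

test_that("undefined metrics are NA with a flag, and MCC handles zero marginals", {
  m <- classification_metrics(list(tp = 0, fn = 0, tn = 4, fp = 1))
  expect_true(is.na(m$sn))
  expect_true("sn" %in% m$undefined)
  expect_equal(m$mcc, 0)
  expect_true("mcc_zero_marginal" %in% m$undefined)
  expect_error(classification_metrics(list(tp = -1, fn = 0, tn = 1, fp = 0)), "negative")
})

test_that("MCC is invariant under swapping the two classes", {
  withr::with_seed(2, {
    for (i in 1:30) {
      cm <- as.list(setNames(sample(0:50, 4, replace = TRUE), c("tp", "tn", "fp", "fn")))
      swapped <- list(tp = cm$tn, tn = cm$tp, fp = cm$fn, fn = cm$fp)
      expect_equal(classification_metrics(cm)$mcc, classification_metrics(swapped)$mcc)
    }
  })
})

test_that("weighted accuracy equals the class-prior mix of Sn and Sp", {
  withr::with_seed(6, {
    for (i in 1:30) {
      cm <- as.list(setNames(sample(1:60, 4, replace = TRUE), c("tp", "tn", "fp", "fn")))
      m <- classification_metrics(cm)
      P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
      expect_equal(m$acc_weighted, (m$sn * P + m$sp * N) / (P + N))
      expect_equal(m$acc_balanced, (m$sn + m$sp) / 2)
    }
  })
})

test_that("ROC/AUC honours ranking, ties and the curve endpoint contract", {
  r <- roc_auc(c(1, 1, -1, -1), c(0.9, 0.8, 0.3, 0.1))
  expect_equal(r$auc, 1)
  tied <- roc_auc(c(1, -1, 1, -1), rep(0.5, 4))
  expect_equal(tied$auc, 0.5)
  mid <- roc_auc(c(1, 1, -1, -1), c(0.9, 0.4, 0.6, 0.2))
  expect_equal(mid$auc, 0.75)
  pts <- mid$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC equals the pairwise-counting oracle on random small inputs", {
  withr::with_seed(17, {
    for (i in 1:150) {
      n <- sample(2:12, 1)
      truth <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # coarse grid forces ties
      expect_equal(roc_auc(truth, scores)$auc, oracle_auc(truth, scores))
    }
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    truth <- sample(c(1, -1), 60, replace = TRUE, prob = c(0.3, 0.7))
    truth[1:2] <- c(1, -1)
    scores <- round(runif(60), 2)
  })
  ours <- roc_auc(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c(-1, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("aggregation returns the per-metric mean and sample SD", {
  tbl <- data.frame(a = c(1, 2, 3), b = c(2, 2, 2))
  agg <- aggregate_metrics(tbl)
  expect_equal(agg$mean, c(2, 2))
  expect_equal(agg$sd, c(1, 0))
  expect_error(aggregate_metrics(tbl[1, , drop = FALSE]), "at least 2")
})

test_that("aggregate_reports summarises evaluation objects", {
  r1 <- evaluate_predictions(c(1, 1, -1, -1), c(0.9, 0.8, 0.2, 0.1))
  r2 <- evaluate_predictions(c(1, 1, -1, -1), c(0.9, 0.1, 0.8, 0.2))
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$metric, c("sn", "sp", "acc_weighted", "acc_balanced", "mcc", "auc"))
  expect_equal(agg$mean[agg$metric == "auc"], mean(c(1, 0.5)))
  same <- aggregate_reports(list(r1, r1))
  expect_true(all(same$sd == 0))
})
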