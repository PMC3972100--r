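test_that("ROC handles the canonical small cases", {
  expect_equal(auc(rocCurve(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))), 1)
  expect_equal(auc(rocCurve(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                         FALSE))), 0.5)
  expect_equal(auc(rocCurve(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))),
               0.75)
})

test_that("curves are anchored and monotone", {
  set.seed(3)
  r <- rocCurve(rnorm(30), rep(c(TRUE, FALSE), 15))
  pts <- rocPoints(r)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_false(is.unsorted(pts$fpr))
  expect_false(is.unsorted(pts$tpr))
})

test_that("degenerate ROC inputs are rejected", {
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "one positive and one")
  expect_error(rocCurve(1:3, c(TRUE, FALSE)), "length mismatch")
  expect_error(rocCurve(1:2, factor(c("a", "b"))), "positive")
})

test_that("trapezoid and pair-counting AUC agree on random instances", {
  set.seed(17)
  for (k in 1:25) {
    n <- sample(5:200, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    r <- rocCurve(scores, labels)  # internal cross-check runs per call
    rk <- rank(scores)
    mw <- (sum(rk[labels]) - sum(labels) * (sum(labels) + 1) / 2) /
      (sum(labels) * sum(!labels))
    expect_equal(auc(r), mw, tolerance = 1e-12)
  }
})

test_that("AUC matches an independent ROC implementation", {
  set.seed(23)
  for (k in 1:5) {
    n <- 80
    labels <- rep(c(TRUE, FALSE), c(30, 50))
    scores <- rnorm(n) + labels
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<")))
    expect_equal(auc(rocCurve(scores, labels)), as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("score negation and label swap flip the AUC", {
  set.seed(5)
  scores <- rnorm(40)  # continuous: ties almost surely absent
  labels <- runif(40) < 0.4
  a <- auc(rocCurve(scores, labels))
  expect_equal(auc(rocCurve(-scores, labels)), 1 - a, tolerance = 1e-12)
  expect_equal(auc(rocCurve(scores, !labels)), 1 - a, tolerance = 1e-12)
})

test_that("early enrichment reports the TPR before the first false positive", {
  expect_equal(tprAtZeroFpr(rocCurve(c(3, 4, 1, 2),
                                     c(TRUE, TRUE, FALSE, FALSE))), 1)
  ## top-ranked item is a negative
  expect_equal(tprAtZeroFpr(rocCurve(c(5, 4, 3), c(FALSE, TRUE, TRUE))), 0)
  expect_equal(tprAtZeroFpr(rocCurve(c(5, 4, 1, 3, 2),
                                     c(TRUE, TRUE, TRUE, FALSE, FALSE))),
               2 / 3)
  ## a positive tied with a negative does not count as enriched
  expect_equal(tprAtZeroFpr(rocCurve(c(2, 1, 1), c(TRUE, TRUE, FALSE))),
               1 / 2)
})

test_that("rank correlation follows Spearman with average ranks", {
  expect_equal(rankCorrelation(1:5, 1:5), 1)
  expect_equal(rankCorrelation(1:5, 5:1), -1)
  expect_equal(rankCorrelation(1:4, c(1, 3, 2, 4)), 0.8)
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rankCorrelation(x, y),
               cor(x, y, method = "spearman"))
  expect_error(rankCorrelation(1:3, 1:4), "length mismatch")
  expect_error(rankCorrelation(c(1, 1, 1), 1:3), "constant")
})

test_that("evaluation reports cover several models on one label set", {
  set.seed(2)
  labels <- rep(c(TRUE, FALSE), c(12, 8))
  rep_ <- evaluationReport(list(good = rnorm(20) + 2 * labels,
                                random = rnorm(20)), labels, "toy")
  expect_equal(nrow(rep_), 2)
  expect_gt(rep_$auc[rep_$model == "good"],
            rep_$auc[rep_$model == "random"])
  expect_equal(rep_$n_pos, c(12, 12))
})
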