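test_that("four-category segment classification follows the threshold rule", {
  tab <- makeScoreTable(perfMeans = c(2.0, 1.0, 2.0, 1.0),
                        voltMeans = c(2.0, 1.0, 1.0, 2.0))
  cls <- classifySegments(tab, threshold = 1.72)
  expect_identical(unname(cls$counts), c(1L, 1L, 1L, 1L))  # TP, TN, FN, FP
  cats <- cls$perSegment$category[order(cls$perSegment$segment)]
  expect_identical(cats, c("TP", "TN", "FN", "FP"))
  # a mean equal to the threshold is viable on both modalities
  eq <- classifySegments(makeScoreTable(1.72, 1.72), 1.72)
  expect_identical(unname(eq$counts["TP"]), 1L)
})

test_that("metrics agree with a brute-force per-segment recount", {
  set.seed(10)
  for (rep in 1:5) {
    p <- round(runif(40, 0, 3), 2)
    v <- round(runif(40, 0, 3), 2)
    thr <- runif(1, 0.5, 2.5)
    cls <- classifySegments(makeScoreTable(p, v), thr)
    oracle <- bruteForceMetrics(p, v, thr)
    expect_identical(cls$counts, oracle$counts)
    expect_equal(cls$metrics, oracle$metrics, tolerance = 1e-12)
    expect_identical(sum(cls$counts), cls$nTotal)   # counts conservation
  }
})

test_that("degenerate counts: perfect prediction and undefined denominators", {
  expect_identical(unname(classificationMetrics(10, 0, 0, 0)[c("concordance", "sensitivity")]),
                   c(100, 100))
  m <- classificationMetrics(0, 5, 0, 0)
  expect_true(is.na(m["sensitivity"]))   # no positives: undefined, not 0
  expect_true(is.na(m["ppv"]))
  expect_error(classificationMetrics(0, 0, 0, 0), "empty")
})

test_that("raising the voltage cutoff never increases sensitivity against fixed truth", {
  set.seed(11)
  p <- round(runif(60, 0, 3), 1)
  v <- pmin(pmax(p + rnorm(60, 0, 0.6), 0), 3)
  roc <- rocSelect(makeScoreTable(p, v))
  # curve cuts are ordered decreasing, so TPR must be non-decreasing along it
  expect_true(all(diff(roc$curve$cut) <= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
  expect_true(all(diff(roc$curve$fpr) >= 0))
})

test_that("ROC selection: perfect separation, Youden choice, permutation null", {
  # identical modality means, separable: AUC 1 and full concordance
  p <- c(rep(0.5, 10), rep(2.5, 10))
  roc <- rocSelect(makeScoreTable(p, p))
  expect_identical(roc$auc, 1)
  cls <- classifySegments(makeScoreTable(p, p), roc$threshold)
  expect_identical(unname(cls$metrics["concordance"]), 100)
  expect_gte(roc$threshold, 0.5)

  # permuted voltage means carry no information: AUC centres on 0.5
  # (operating threshold fixed from the unpermuted data; re-selecting it per
  # permutation would bias the null upward)
  set.seed(12)
  p2 <- round(runif(60, 0, 3), 1)
  v2 <- pmin(pmax(p2 + rnorm(60, 0, 0.4), 0), 3)
  thr0 <- rocSelect(makeScoreTable(p2, v2))$threshold
  aucs <- vapply(1:200, function(i) {
    rocSelect(makeScoreTable(p2, sample(v2)), threshold = thr0)$auc
  }, numeric(1))
  expect_lt(abs(median(aucs) - 0.5), 0.1)

  expect_error(rocSelect(makeScoreTable(rep(2, 5), rep(2, 5))), "distinct")
})

test_that("trapezoidal AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  p <- round(runif(50, 0, 3), 1)
  v <- pmin(pmax(p + rnorm(50, 0, 0.8), 0), 3)
  tab <- makeScoreTable(p, v)
  roc <- rocSelect(tab)
  truth <- p >= roc$threshold
  ref <- pROC::roc(response = truth, predictor = v, quiet = TRUE,
                   direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("the reconstructed study 2x2 table reproduces all printed metrics", {
  m <- classificationMetrics(TP = 87, TN = 130, FN = 55, FP = 40)
  expect_identical(87 + 130 + 55 + 40, 312)
  expect_identical(round(unname(m["concordance"])), 70)
  expect_identical(round(unname(m["concordance"]), 1), 69.6)
  expect_identical(round(unname(m["sensitivity"]), 1), 61.3)
  expect_identical(round(unname(m["specificity"]), 1), 76.5)
  expect_identical(round(unname(m["ppv"]), 1), 68.5)
  expect_identical(round(unname(m["npv"]), 1), 70.3)
})
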