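test_that("confusion metrics match the direct formula on a worked example", {
  cm <- crproles:::computeMetrics(tp = 10, fp = 2, tn = 42, fn = 2)
  expect_equal(cm@mcc, 416 / 528)
  expect_equal(cm@acc, 52 / 56)
  expect_equal(round(cm@mcc, 2), 0.79)
  expect_equal(round(cm@acc, 2), 0.93)

  # perfect prediction
  p <- c(rep("repressor", 5), rep("activator", 7))
  cmP <- confusionMetrics(p, p)
  expect_equal(c(cmP@acc, cmP@sen, cmP@spe, cmP@mcc), rep(1, 4))

  # all-activator prediction on mixed truth: SEN 0, MCC 0 by convention
  cmA <- confusionMetrics(p, rep("activator", 12))
  expect_equal(cmA@sen, 0)
  expect_equal(cmA@mcc, 0)

  expect_error(confusionMetrics(p, p[-1]), "equal length")
})

test_that("published class sizes and SEN/SPE reconstruct the printed ACC and MCC", {
  # test split: 12 repressors, 44 activators, SEN 0.83, SPE 0.95
  tst <- reconstructConfusion(nPos = 12, nNeg = 44, sen = 0.83, spe = 0.95)
  expect_equal(c(tst@tp, tst@fn, tst@tn, tst@fp), c(10, 2, 42, 2))
  expect_equal(round(tst@mcc, 2), 0.79)
  expect_equal(round(tst@acc, 2), 0.93)
  # training split: 24 repressors, 89 activators, SEN 0.92, SPE 1.00
  trn <- reconstructConfusion(nPos = 24, nNeg = 89, sen = 0.92, spe = 1.00)
  expect_equal(round(trn@mcc, 2), 0.95)
  expect_equal(round(trn@acc, 2), 0.98)
})

test_that("metrics agree with a counting oracle on random vectors", {
  crproles:::withSeed(37, {
    for (i in 1:1000) {
      n <- sample(4:40, 1)
      truth <- sample(c("activator", "repressor"), n, replace = TRUE)
      pred <- sample(c("activator", "repressor"), n, replace = TRUE)
      cm <- confusionMetrics(truth, pred)
      tp <- sum(truth == "repressor" & pred == "repressor")
      fp <- sum(truth == "activator" & pred == "repressor")
      tn <- sum(truth == "activator" & pred == "activator")
      fn <- sum(truth == "repressor" & pred == "activator")
      expect_equal(c(cm@tp, cm@fp, cm@tn, cm@fn),
                   c(tp, fp, tn, fn), ignore_attr = TRUE)
      expect_equal(cm@acc, (tp + tn) / n)
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      expect_equal(cm@mcc, if (den == 0) 0 else (tp * tn - fp * fn) / den)
    }
  })
})

test_that("swapping the positive class exchanges SEN/SPE and negates MCC", {
  crproles:::withSeed(41, {
    for (i in 1:50) {
      n <- 30
      truth <- sample(c("activator", "repressor"), n, replace = TRUE)
      pred <- sample(c("activator", "repressor"), n, replace = TRUE)
      a <- confusionMetrics(truth, pred, positive = "repressor")
      b <- confusionMetrics(truth, pred, positive = "activator")
      expect_equal(a@sen, b@spe)
      expect_equal(a@spe, b@sen)
      expect_equal(a@mcc, b@mcc)  # MCC is symmetric under class exchange
      expect_equal(a@acc, b@acc)
    }
  })
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney oracle", {
  y <- c(rep("repressor", 4), rep("activator", 4))
  expect_equal(rocAuc(c(4, 3.5, 3, 2.9, 2, 1, 0.5, 0.1), y)$auc, 1.0)
  expect_equal(rocAuc(rep(1, 8), y)$auc, 0.5)
  expect_error(rocAuc(1:4, rep("activator", 4)), "positive")

  pairwiseAuc <- function(scores, truth) {
    sp <- scores[truth == "repressor"]; sn <- scores[truth == "activator"]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  crproles:::withSeed(43, {
    n <- 200
    truth <- sample(c("activator", "repressor"), n, replace = TRUE,
                    prob = c(0.7, 0.3))
    scores <- round(stats::rnorm(n), 1)  # rounding forces ties
    r <- rocAuc(scores, truth)
    expect_equal(r$auc, pairwiseAuc(scores, truth), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(rocAuc(exp(scores), truth)$auc, r$auc, tolerance = 1e-12)
    # ROC endpoints
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
  })
})
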