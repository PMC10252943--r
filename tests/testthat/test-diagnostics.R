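test_that("classification metrics count the confusion table correctly", {
  # TP=3, FN=1, TN=4, FP=0
  y <- c(rep(1, 4), rep(-1, 4))
  yhat <- c(2, 1, 0.5, -0.2, -1, -2, -0.5, -0.1)
  m <- classificationMetrics(y, yhat)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.875)
  expect_equal(m$nmc, 1)

  all_right <- classificationMetrics(y, y)
  expect_equal(unlist(all_right), c(sensitivity = 1, specificity = 1,
                                    accuracy = 1, nmc = 0))
  all_wrong <- classificationMetrics(y, -y)
  expect_equal(unlist(all_wrong), c(sensitivity = 0, specificity = 0,
                                    accuracy = 0, nmc = 8))
  # a prediction exactly at the threshold classifies as NI
  expect_equal(classificationMetrics(c(1, -1), c(0, -1))$nmc, 1)
})

test_that("Q2 and DQ2 reproduce their hand-computed examples", {
  y <- c(-1, -1, 1, 1)
  expect_equal(q2(y, y), 1)
  expect_equal(q2(y, rep(mean(y), 4)), 0)
  expect_equal(q2(y, c(-0.5, -1.5, 0.5, 1.5)), 0.75)

  # predictions at or beyond the class target carry no DQ2 penalty
  expect_equal(dq2(y, c(-1.2, -1.0, 1.0, 1.4)), 1)
  expect_equal(dq2(y, c(-0.5, -1.5, 0.5, 1.5)), 0.875)
  expect_equal(dq2(y, rep(0, 4)), 0)
  expect_error(q2(rep(1, 4), rep(1, 4)), "class")
})

test_that("DQ2 dominates Q2 on random codings", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    y <- c(rep(-1, ceiling(n / 2)), rep(1, floor(n / 2)))[sample(n)]
    if (length(unique(y)) < 2) next
    yhat <- rnorm(n, 0.6 * y, 1)
    expect_gte(dq2(y, yhat), q2(y, yhat))
  }
})

test_that("AUROC equals the all-pairs oracle and handles ties", {
  y <- c(-1, -1, 1, 1)
  expect_equal(auroc(y, c(-1, 0, 0, 1)), 0.875)
  expect_equal(auroc(y, c(-2, -1, 1, 2)), 1)
  expect_equal(auroc(y, c(2, 1, -1, -2)), 0)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    y <- ifelse(runif(n) < 0.5, -1, 1)
    if (length(unique(y)) < 2) next
    yhat <- round(rnorm(n, 0.4 * y), 1)   # rounding forces ties
    expect_equal(auroc(y, yhat), aurocOracle(y, yhat))
  }
})

test_that("tRMSECV rescales the scan range with its endpoints fixed", {
  expect_equal(trmsecv(0.1, 0.1, 0.5), 1)
  expect_equal(trmsecv(0.5, 0.1, 0.5), 0)
  expect_equal(trmsecv(0.3, 0.1, 0.5), 0.5 * (0.1 / 0.3))
  expect_equal(trmsecv(0.2, 0.2, 0.2), 1)     # degenerate range
  expect_error(trmsecv(0.6, 0.1, 0.5), "within")
  # monotone non-increasing over the scan interval
  xs <- seq(0.1, 0.5, length.out = 30)
  vals <- vapply(xs, trmsecv, numeric(1), min = 0.1, max = 0.5)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("the efficiency index is the plain sum of its seven terms", {
  mk <- function(q2v, dq2v, acc, sens, spec, auc, tr)
    methods::new("DiagnosticSet", q2 = q2v, dq2 = dq2v, sensitivity = sens,
                 specificity = spec, accuracy = acc, auroc = auc,
                 rmsecv = 0.3, trmsecv = tr, iEff = NA_real_,
                 nmc = 0, n = 4L)
  expect_equal(iEff(mk(1, 1, 1, 1, 1, 1, 1)), 7)
  expect_equal(iEff(mk(0.75, 0.875, 1, 1, 1, 1, 0.5)), 6.125)
  # a catastrophic Q2 can push the index below zero
  expect_lt(iEff(mk(-9, 0, 0.5, 0.5, 0.5, 0.5, 0)), 0)
  expect_error(iEff(mk(NA_real_, 1, 1, 1, 1, 1, 1)), "component")
})

test_that("diagnosticSet assembles consistent statistics", {
  y <- c(-1, -1, 1, 1)
  yhat <- c(-0.5, -1.5, 0.5, 1.5)
  d <- diagnosticSet(y, yhat, rmsecvRange = c(0.25, 1))
  expect_equal(d@q2, 0.75)
  expect_equal(d@dq2, 0.875)
  expect_equal(d@accuracy, 1 - d@nmc / 4)
  expect_equal(d@rmsecv, sqrt(sum((y - yhat)^2) / 4))
  expect_equal(d@iEff, d@q2 + d@dq2 + d@accuracy + d@sensitivity +
                 d@specificity + d@auroc + d@trmsecv)
  # without a scan range the scan-relative parts stay NA
  d2 <- diagnosticSet(y, yhat)
  expect_true(is.na(d2@trmsecv) && is.na(d2@iEff))
})
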