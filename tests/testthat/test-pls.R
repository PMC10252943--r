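test_that("one latent variable on one predictor is simple regression", {
  tab <- makeToyTable(n_inf = 1, n_noise = 0, nPerClass = 5, seed = 2)
  m <- fitPLS(tab, nLV = 1)
  pr <- predictPLS(m, tab)
  x <- areaMatrix(tab)[, 1]
  y <- classCoding(tab)
  expect_equal(pr$yhat, unname(fitted(lm(y ~ x))), tolerance = 1e-10)
})

test_that("full-rank PLS predictions equal ordinary least squares", {
  for (seed in c(1, 2, 3)) {
    tab <- makeRandomTable(n = 8, p = 5, seed = seed)
    y <- classCoding(tab)
    m <- fitPLS(tab, nLV = 5)
    pr <- predictPLS(m, tab)
    ols <- unname(fitted(lm(y ~ areaMatrix(tab))))
    expect_equal(pr$yhat, ols, tolerance = 1e-8)
  }
})

test_that("training scores are mutually orthogonal", {
  tab <- makeRandomTable(n = 10, p = 8, seed = 4)
  m <- fitPLS(tab, nLV = 4)
  G <- crossprod(m@scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
})

test_that("the fit is invariant to run order", {
  tab <- makeToyTable(seed = 5)
  set.seed(1)
  perm <- sample(nRuns(tab))
  m1 <- fitPLS(tab, nLV = 3)
  m2 <- fitPLS(tab[, perm], nLV = 3)
  expect_equal(m1@weights, m2@weights, tolerance = 1e-10)
  expect_equal(m1@yLoadings, m2@yLoadings, tolerance = 1e-10)
})

test_that("prediction is invariant to constant column shifts", {
  tab <- makeToyTable(seed = 6)
  X2 <- areaMatrix(tab)
  X2[, 1] <- X2[, 1] + 500
  tab2 <- LipidFeatureTable(X2, classes = as.character(classLabels(tab)))
  m1 <- fitPLS(tab, nLV = 2)
  m2 <- fitPLS(tab2, nLV = 2)
  p1 <- predictPLS(m1, tab)$yhat
  p2 <- predictPLS(m2, tab2)$yhat
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("a separable training set is perfectly reclassified", {
  tab <- makeToyTable(delta = 6, seed = 7)
  m <- fitPLS(tab, nLV = 2)
  pr <- predictPLS(m, tab)
  expect_equal(as.character(pr$class), as.character(classLabels(tab)))
})

test_that("a model on two informative markers transfers to new draws", {
  markers <- c("PS (16:0_18:3)", "PE (18:3_18:3)")
  tab <- lipidView(generateDataset(generatorConfig(seed = 8)), markers)
  test_tab <- lipidView(generateDataset(generatorConfig(seed = 9)), markers)
  m <- fitPLS(tab, nLV = 2)
  pr <- predictPLS(m, test_tab)
  expect_gt(mean(pr$class == classLabels(test_tab)), 0.75)
})

test_that("VIP scores satisfy their normalisation and ordering", {
  tab1 <- makeToyTable(n_inf = 1, n_noise = 0, nPerClass = 5, seed = 10)
  expect_equal(unname(vipScores(fitPLS(tab1, nLV = 1))), 1)

  tab <- makeToyTable(n_inf = 2, n_noise = 3, delta = 5, seed = 11)
  m <- fitPLS(tab, nLV = 2)
  v <- vipScores(m)
  expect_equal(sum(v^2), length(v), tolerance = 1e-8)
  expect_true(all(v[1:2] > 1))          # informative lipids
  expect_true(all(v[1:2] > max(v[3:5])))
})

test_that("zero-variance lipids are dropped with a record", {
  tab <- makeToyTable(seed = 12)
  X <- areaMatrix(tab)
  X[, 3] <- 7
  tab2 <- LipidFeatureTable(X, classes = as.character(classLabels(tab)))
  expect_message(m <- fitPLS(tab2, nLV = 2), "zero-variance")
  expect_equal(m@dropped, colnames(X)[3])
  expect_length(vipScores(m), 4)
})

test_that("models serialize to JSON and predict identically after reload", {
  tab <- makeToyTable(seed = 13)
  m <- fitPLS(tab, nLV = 2)
  f <- tempfile(fileext = ".json")
  writePLSModel(m, f)
  m2 <- readPLSModel(f)
  expect_equal(predictPLS(m2, tab)$yhat, predictPLS(m, tab)$yhat,
               tolerance = 1e-12)
})

test_that("fit preconditions are enforced", {
  tab <- makeToyTable(nPerClass = 4, seed = 14)
  expect_error(fitPLS(tab, nLV = 20), "nLV")
  one_class <- LipidFeatureTable(areaMatrix(tab), classes = rep("NI", 8))
  expect_error(fitPLS(one_class, nLV = 1), "both classes")
  m <- fitPLS(tab, nLV = 2)
  expect_error(predictPLS(m, tab[1:2, ]), "lacks")
})
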