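test_that("two-group ANOVA p-values match stats::aov per lipid", {
  tab <- makeToyTable(n_inf = 2, n_noise = 3, delta = 1.5, seed = 1)
  sel <- volcanoStats(tab)
  X <- areaMatrix(tab)
  g <- classLabels(tab)
  for (j in c(1, 3, 5)) {
    p_ref <- summary(aov(X[, j] ~ g))[[1]][["Pr(>F)"]][1]
    expect_equal(sel$p_value[j], p_ref, tolerance = 1e-10)
  }
})

test_that("threshold phrasings agree: p <= 0.05 iff -log10 p >= 1.3", {
  tab <- generateDataset(generatorConfig(seed = 2))
  sel <- volcanoStats(ionModeView(tab, "negative"))
  # 10^-1.3 = 0.0501...; the two printed rules coincide up to rounding
  expect_equal(sel$p_value <= 0.05,
               sel$neg_log10_p >= -log10(0.05))
  expect_lt(sum((sel$p_value <= 10^-1.3) != (sel$p_value <= 0.05)), 2)
})

test_that("degenerate lipids follow the exact-equality rule", {
  X <- cbind("PE (const)" = rep(5, 8), "PC (split)" = rep(c(2, 9), each = 4),
             "PI (x)" = runif(8, 1, 2))
  tab <- LipidFeatureTable(X, classes = rep(c("NI", "IRR"), each = 4))
  expect_message(sel <- volcanoStats(tab), "zero within-class variance")
  expect_equal(sel$p_value[sel$lipid == "PE (const)"], 1)
  expect_equal(sel$log2_fc[sel$lipid == "PE (const)"], 0)
  expect_equal(sel$p_value[sel$lipid == "PC (split)"], 0)
})

test_that("a strong published marker is detected in nearly every draw", {
  hits <- vapply(1:20, function(s) {
    tab <- generateDataset(generatorConfig(seed = 100 + s))
    sub <- lipidView(tab, "PS (16:0_18:3)")
    X <- areaMatrix(sub)
    y <- classLabels(sub)
    t.test(X[y == "IRR", 1], X[y == "NI", 1], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gte(mean(hits <= 0.05), 0.95)
})

test_that("PLS-DA selection applies both rules jointly", {
  tab <- makeToyTable(n_inf = 2, n_noise = 4, delta = 4, nPerClass = 8,
                      seed = 3)
  sel <- volcanoStats(tab)
  m <- fitPLS(tab, nLV = 2)
  out <- selectPLSDAMarkers(tab, m, sel)
  expect_true(all(out$selected_plsda ==
                    (out$p_value <= 0.05 & out$vip >= 1)))
  expect_true(all(out$selected_plsda[1:2]))
  expect_false(any(out$selected_plsda[3:6]))
  # rule application on explicit values
  fake <- out
  fake$p_value[3] <- 0.04; fake$vip[3] <- 0.9
  fake$selected_plsda <- fake$p_value <= 0.05 & fake$vip >= 1
  expect_false(fake$selected_plsda[3])
})

test_that("most generated catalog markers are recovered by the screen", {
  cat42 <- loadMarkerCatalog()
  plsda_ids <- cat42$lipid_id[vapply(cat42$marker_models, function(m)
    "PLS-DA" %in% m, logical(1))]
  recovery <- vapply(1:5, function(s) {
    tab <- generateDataset(generatorConfig(seed = 200 + s))
    hits <- 0L
    for (mode in c("negative", "positive")) {
      v <- ionModeView(tab, mode)
      sel <- selectPLSDAMarkers(v, fitPLS(v, nLV = 3), volcanoStats(v))
      hits <- hits + sum(sel$lipid %in% plsda_ids & sel$selected_plsda)
    }
    hits / length(plsda_ids)
  }, numeric(1))
  expect_gte(median(recovery), 0.8)
})

test_that("selection flags are invariant to run order", {
  tab <- makeToyTable(seed = 4)
  set.seed(5)
  perm <- sample(nRuns(tab))
  s1 <- selectPLSDAMarkers(tab, fitPLS(tab, nLV = 2), volcanoStats(tab))
  tp <- tab[, perm]
  s2 <- selectPLSDAMarkers(tp, fitPLS(tp, nLV = 2), volcanoStats(tp))
  expect_equal(s1$selected_plsda, s2$selected_plsda)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
})

test_that("LDA preparation caps, ranks and log-transforms correctly", {
  set.seed(6)
  n <- 12
  p <- 30
  X <- matrix(NA_real_, 2 * n, p)
  shift <- seq(2, 0.5, length.out = p)
  for (j in seq_len(p))
    X[, j] <- c(rnorm(n, 10, 1), rnorm(n, 10 + shift[j], 1))
  X <- pmax(X, 1e-3)
  colnames(X) <- sprintf("PE (v%02d)", seq_len(p))
  tab <- LipidFeatureTable(X, classes = rep(c("NI", "IRR"), each = n))
  sel <- volcanoStats(tab)
  prep <- prepareLDAVariables(tab, sel)
  expect_lte(nLipids(prep$table), n)
  kept_p <- sel$p_value[match(rownames(prep$table), sel$lipid)]
  dropped_p <- sel$p_value[sel$p_value <= 0.05 &
                             !sel$lipid %in% rownames(prep$table)]
  if (length(dropped_p)) expect_lte(max(kept_p), min(dropped_p))

  # a strongly lognormal lipid fails Lilliefors and gets logged
  set.seed(7)
  Y <- cbind("PC (norm)" = c(rnorm(12, 20, 1), rnorm(12, 26, 1)),
             "PC (lnorm)" = exp(c(rnorm(12, 1, 1), rnorm(12, 3, 1))))
  tab2 <- LipidFeatureTable(pmax(Y, 1e-3),
                            classes = rep(c("NI", "IRR"), each = 12))
  prep2 <- prepareLDAVariables(tab2, volcanoStats(tab2))
  tr <- prep2$transforms
  expect_false(tr$log_transformed[tr$lipid == "PC (norm)"])
  expect_true(tr$log_transformed[tr$lipid == "PC (lnorm)"])
  expect_equal(areaMatrix(prep2$table)[, "PC (lnorm)"],
               log(Y[, "PC (lnorm)"]), ignore_attr = TRUE)
})
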