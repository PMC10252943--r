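test_that("default generation reproduces the study layout exactly", {
  tab <- generateDataset(generatorConfig(seed = 3))
  expect_equal(nRuns(tab), 24L)
  expect_equal(nLipids(tab), 479L)
  lm <- lipidMeta(tab)
  expect_equal(length(unique(lm$subclass)), 16L)
  expect_true(all(areaMatrix(tab) > 0))

  # census conformance, cell by cell
  cen <- loadSubclassCensus()
  got <- aggregate(rep(1L, nrow(lm)),
                   by = list(subclass = lm$subclass, ion_mode = lm$ion_mode,
                             oxidation = lm$oxidation), FUN = sum)
  for (i in seq_len(nrow(cen))) {
    hit <- got$subclass == cen$subclass[i] &
      got$ion_mode == cen$ion_mode[i] & got$oxidation == cen$oxidation[i]
    expect_equal(sum(got$x[hit]), cen$n[i],
                 label = paste(cen$subclass[i], cen$oxidation[i]))
  }
  # class design: 4 cheeses x 3 replicates per class
  rm <- runMeta(tab)
  expect_equal(unname(table(rm$class)), c(12L, 12L), ignore_attr = TRUE)
  expect_equal(sort(unique(rm$cheese)), 1:4)
  expect_equal(sort(unique(rm$replicate)), 1:3)
})

test_that("identical configs give identical tables; seeds change them", {
  a <- generateDataset(generatorConfig(seed = 9))
  b <- generateDataset(generatorConfig(seed = 9))
  c <- generateDataset(generatorConfig(seed = 10))
  expect_identical(areaMatrix(a), areaMatrix(b))
  expect_false(identical(areaMatrix(a), areaMatrix(c)))
})

test_that("marker draws track the catalog means within sampling error", {
  cat42 <- loadMarkerCatalog()
  # i.i.d. runs so the SE of the class mean is sd/sqrt(12)
  tab <- generateDataset(generatorConfig(seed = 21, cheeseEffectSdFrac = 0))
  y <- classLabels(tab)
  X <- areaMatrix(tab)
  ps <- cat42[cat42$lipid_id == "PS (16:0_18:3)", ]
  mNI <- mean(X[y == "NI", "PS (16:0_18:3)"])
  expect_lt(abs(mNI - ps$mean_NI), 3 * ps$sd_NI / sqrt(12))

  # separation directions in expectation over markers (averaged over runs)
  oxtg <- "TG (18:2+O_18:0_18:0)"
  expect_gt(mean(X[y == "IRR", oxtg]), mean(X[y == "NI", oxtg]))
  pe <- "PE (18:3_18:3)"
  expect_lt(mean(X[y == "IRR", pe]), mean(X[y == "NI", pe]))
})

test_that("the null generator removes every class effect", {
  # i.i.d. runs: the F-test's independence assumption holds exactly
  tab <- generateNullDataset(generatorConfig(seed = 31,
                                             cheeseEffectSdFrac = 0))
  sel <- volcanoStats(tab)
  # valid test under H0: about 5% of 479 lipids below p = 0.05
  expect_gt(mean(sel$p_value <= 0.05), 0.02)
  expect_lt(mean(sel$p_value <= 0.05), 0.09)
  # markers centred on the pooled mean in both classes
  X <- areaMatrix(tab)
  y <- classLabels(tab)
  cat42 <- loadMarkerCatalog()
  ps <- cat42[cat42$lipid_id == "PS (16:0_18:3)", ]
  pooled <- (ps$mean_NI + ps$mean_IRR) / 2
  ps_sd <- sqrt((ps$sd_NI^2 + ps$sd_IRR^2) / 2)
  expect_lt(abs(mean(X[, "PS (16:0_18:3)"]) - pooled), 4 * ps_sd / sqrt(24))
})

test_that("the lognormal option also matches the catalog moments", {
  cfg <- generatorConfig(seed = 41, distribution = "lognormal",
                        cheeseEffectSdFrac = 0)
  tab <- generateDataset(cfg)
  X <- areaMatrix(tab)
  y <- classLabels(tab)
  cat42 <- loadMarkerCatalog()
  pe <- cat42[cat42$lipid_id == "PE (18:1_18:2)", ]  # low-CV marker
  expect_lt(abs(mean(X[y == "NI", "PE (18:1_18:2)"]) - pe$mean_NI),
            4 * pe$sd_NI / sqrt(12))
  expect_true(all(X > 0))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig(nCheesesPerClass = 0), "counts")
  expect_error(generatorConfig(cheeseEffectSdFrac = 1), "cheeseEffectSdFrac")
  expect_error(generatorConfig(nonmarkerCV = 0), "nonmarkerCV")
})
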