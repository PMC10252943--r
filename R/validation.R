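.DIAG_COLS <- c("q2", "dq2", "sensitivity", "specificity", "accuracy",
                "auroc", "rmsecv", "trmsecv", "i_eff", "nmc", "n")

.diagVec <- function(d)
  c(d@q2, d@dq2, d@sensitivity, d@specificity, d@accuracy, d@auroc,
    d@rmsecv, d@trmsecv, d@iEff, d@nmc, d@n)

.makeReport <- function(protocol, diagnostics, nLV, seed,
                        modalLV = NA_real_, extra = list()) {
  num <- diagnostics[, setdiff(colnames(diagnostics), "n"), drop = FALSE]
  summ <- rbind(mean = colMeans(num, na.rm = TRUE),
                sd = apply(num, 2, sd, na.rm = TRUE))
  methods::new("ValidationReport", protocol = protocol,
               diagnostics = diagnostics, summary = as.data.frame(summ),
               nLV = nLV, modalLV = modalLV, seed = as.numeric(seed),
               extra = extra)
}

#' Summarise a validation report
#'
#' @param object a [ValidationReport-class].
#' @param ... unused.
#' @return The mean/sd summary `data.frame` (statistics in columns).
#' @export
setMethod("summary", "ValidationReport", function(object, ...)
  object@summary)

#' @describeIn ValidationReport-class compact display.
#' @param object a `ValidationReport`.
#' @export
setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport [", object@protocol, "]: ",
      nrow(object@diagnostics), " repetition(s)\n", sep = "")
  if (!is.na(object@modalLV))
    cat("  modal #LV:", object@modalLV, "\n")
  else if (!all(is.na(object@nLV)))
    cat("  #LV:", object@nLV[1], "\n")
  print(round(object@summary, 4))
})

# stratified fold assignment: within each class, shuffled indices are
# dealt round-robin over k folds
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# inner-loop #LV selection: stratified foldsInner-fold CV on (X, y)
# scanning 1..maxLV, efficiency index on pooled inner-validation
# predictions; returns the selected #LV (ties -> fewest components)
.selectLV <- function(X, y, maxLV, foldsInner, autoscale) {
  n <- length(y)
  maxLV <- min(maxLV, n - ceiling(n / foldsInner) - 1L, ncol(X))
  if (maxLV < 1L) maxLV <- 1L
  fold <- .stratifiedFolds(y, foldsInner)
  pred <- matrix(NA_real_, n, maxLV)
  for (f in seq_len(foldsInner)) {
    tr <- fold != f
    a <- min(maxLV, sum(tr) - 1L)
    fit <- .fitPLSMat(X[tr, , drop = FALSE], y[tr], a, autoscale)
    ph <- .predPLSAllMat(fit, X[!tr, , drop = FALSE])
    if (fit$nLV < maxLV)  # rank-deficient training part: extend last LV
      ph <- cbind(ph, ph[, rep(fit$nLV, maxLV - fit$nLV), drop = FALSE])
    pred[!tr, ] <- ph[, seq_len(maxLV), drop = FALSE]
  }
  rms <- sqrt(colMeans((y - pred)^2))
  ieff <- vapply(seq_len(maxLV), function(a) {
    d <- diagnosticSet(y, pred[, a], rmsecvRange = range(rms))
    d@iEff
  }, numeric(1))
  which.max(ieff)
}

#' Repeated double cross-validation of PLS-DA
#'
#' The reference protocol for both tuning and assessing the PLS-DA
#' model. Each repetition draws stratified outer folds; within each
#' outer training portion an inner stratified cross-validation scans
#' `1..maxLV` latent variables and picks the count maximising the
#' efficiency index ([iEff()]) of the pooled inner-validation
#' predictions (with tRMSECV rescaled over that scan's RMSECV range).
#' The model is refit at the selected count on the outer training
#' portion and scored on the outer test fold; the repetition's
#' diagnostics come from the pooled outer-test predictions. Averages
#' over repetitions estimate performance; the modal selected count is
#' the protocol's latent-variable choice.
#'
#' @param table a [LipidFeatureTable-class].
#' @param maxLV largest latent-variable count scanned (default 10).
#' @param repetitions number of repetitions (default 200).
#' @param foldsOuter,foldsInner stratified fold counts (defaults 4
#'   and 5).
#' @param autoscale passed to the PLS fits.
#' @param seed integer RNG seed.
#' @return A [ValidationReport-class]; `@modalLV` holds the modal
#'   selected latent-variable count and `@extra$chosenLV` the
#'   per-outer-fold selections.
#' @examples
#' \donttest{
#' tab <- ionModeView(generateDataset(generatorConfig(seed = 1)), "negative")
#' rep <- doubleCrossValidation(tab, repetitions = 10, seed = 2)
#' summary(rep)
#' }
#' @export
doubleCrossValidation <- function(table, maxLV = 10, repetitions = 200,
                                  foldsOuter = 4, foldsInner = 5,
                                  autoscale = TRUE, seed = 1L) {
  .assertTwoClass(table, min_per_class = foldsOuter,
                  what = "doubleCrossValidation")
  X <- areaMatrix(table)
  y <- classCoding(table)
  set.seed(seed)
  rows <- matrix(NA_real_, repetitions, length(.DIAG_COLS),
                 dimnames = list(NULL, .DIAG_COLS))
  chosen <- matrix(NA_integer_, repetitions, foldsOuter)
  for (r in seq_len(repetitions)) {
    fold <- .stratifiedFolds(y, foldsOuter)
    yhat <- numeric(length(y))
    for (f in seq_len(foldsOuter)) {
      tr <- fold != f
      a <- .selectLV(X[tr, , drop = FALSE], y[tr], maxLV, foldsInner,
                     autoscale)
      chosen[r, f] <- a
      fit <- .fitPLSMat(X[tr, , drop = FALSE], y[tr], a, autoscale)
      yhat[!tr] <- .predPLSAllMat(fit, X[!tr, , drop = FALSE])[, fit$nLV]
    }
    rows[r, ] <- .diagVec(diagnosticSet(y, yhat))
  }
  modal <- which.max(tabulate(as.vector(chosen)))  # ties -> fewest LVs
  .makeReport("double_cv", as.data.frame(rows), nLV = NA_real_, seed = seed,
              modalLV = modal, extra = list(chosenLV = chosen))
}

#' Bootstrap validation of PLS-DA at a fixed latent-variable count
#'
#' Each iteration draws `n` training runs with replacement; the
#' out-of-bag runs (on average `~0.368 n`, i.e. a validation share of
#' `1 - (1 - 1/n)^n`) form the validation set. A draw whose training
#' part lacks a class, or with an empty out-of-bag set, is redrawn
#' (fatal after 1000 consecutive redraws). Class-conditional statistics
#' undefined on a one-class out-of-bag set are `NA` for that iteration
#' and excluded from the averages.
#'
#' @param table a [LipidFeatureTable-class].
#' @param iterations number of bootstrap iterations (default 10000).
#' @param nLV fixed latent-variable count (take it from
#'   [doubleCrossValidation()]).
#' @param autoscale passed to the PLS fits.
#' @param seed integer RNG seed.
#' @return A [ValidationReport-class].
#' @export
bootstrapValidation <- function(table, iterations = 10000, nLV,
                                autoscale = TRUE, seed = 1L) {
  .assertTwoClass(table, what = "bootstrapValidation")
  X <- areaMatrix(table)
  y <- classCoding(table)
  n <- length(y)
  set.seed(seed)
  rows <- matrix(NA_real_, iterations, length(.DIAG_COLS),
                 dimnames = list(NULL, .DIAG_COLS))
  redraws <- 0L
  for (r in seq_len(iterations)) {
    repeat {
      tr <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), tr)
      if (length(unique(y[tr])) == 2L && length(oob) > 0L) break
      redraws <- redraws + 1L
      if (redraws >= 1000L)
        stop("bootstrap: 1000 consecutive degenerate draws")
    }
    redraws <- 0L
    a <- min(nLV, n - 1L)
    fit <- .fitPLSMat(X[tr, , drop = FALSE], y[tr], a, autoscale)
    yh <- .predPLSAllMat(fit, X[oob, , drop = FALSE])[, fit$nLV]
    yo <- y[oob]
    rows[r, ] <- if (length(unique(yo)) == 2L)
      .diagVec(diagnosticSet(yo, yh))
    else
      .diagVec(.oneClassDiagnostics(yo, yh))
  }
  .makeReport("bootstrap", as.data.frame(rows), nLV = as.numeric(nLV),
              seed = seed)
}

# metrics on a one-class validation set (possible for bootstrap OOB):
# only accuracy/NMC/RMSECV and the defined one of sens/spec survive
.oneClassDiagnostics <- function(y, yhat) {
  cm <- classificationMetrics(y, yhat)
  methods::new("DiagnosticSet", q2 = NA_real_, dq2 = NA_real_,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               accuracy = cm$accuracy, auroc = NA_real_,
               rmsecv = rmsecv(y, yhat), trmsecv = NA_real_,
               iEff = NA_real_, nmc = cm$nmc, n = length(y))
}

#' Stratified random subsampling validation at a fixed #LV
#'
#' Each iteration splits the runs into training and validation subsets
#' at `trainFraction` (default 3:1) within each class, preserving the
#' class proportions in both subsets, fits PLS-DA on the training part
#' and scores the validation part.
#'
#' @inheritParams bootstrapValidation
#' @param trainFraction per-class training fraction (default 0.75).
#' @return A [ValidationReport-class].
#' @export
subsamplingValidation <- function(table, iterations = 10000,
                                  trainFraction = 0.75, nLV,
                                  autoscale = TRUE, seed = 1L) {
  .assertTwoClass(table, min_per_class = 2L, what = "subsamplingValidation")
  X <- areaMatrix(table)
  y <- classCoding(table)
  idx1 <- which(y == 1); idx0 <- which(y == -1)
  k1 <- round(trainFraction * length(idx1))
  k0 <- round(trainFraction * length(idx0))
  if (k1 < 1L || k0 < 1L || k1 >= length(idx1) || k0 >= length(idx0))
    stop("infeasible stratification at trainFraction = ", trainFraction)
  set.seed(seed)
  rows <- matrix(NA_real_, iterations, length(.DIAG_COLS),
                 dimnames = list(NULL, .DIAG_COLS))
  for (r in seq_len(iterations)) {
    tr <- c(sample(idx1, k1), sample(idx0, k0))
    a <- min(nLV, length(tr) - 1L)
    fit <- .fitPLSMat(X[tr, , drop = FALSE], y[tr], a, autoscale)
    yh <- .predPLSAllMat(fit, X[-tr, , drop = FALSE])[, fit$nLV]
    rows[r, ] <- .diagVec(diagnosticSet(y[-tr], yh))
  }
  .makeReport("subsampling", as.data.frame(rows), nLV = as.numeric(nLV),
              seed = seed)
}

# greedy max-min selection over a distance matrix restricted to
# `pool` (original indices); ties broken by lowest run index
.ksGreedy <- function(D, pool, k) {
  Dp <- D[pool, pool, drop = FALSE]
  np <- length(pool)
  # seed pair: mutually farthest, lexicographically smallest on ties
  mx <- max(Dp)
  hit <- which(Dp == mx, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- c(hit[1, 1], hit[1, 2])
  while (length(sel) < k) {
    cand <- setdiff(seq_len(np), sel)
    dmin <- apply(Dp[cand, sel, drop = FALSE], 1, min)
    best <- cand[dmin == max(dmin)]
    sel <- c(sel, min(best))
  }
  pool[sel]
}

#' Kennard-Stone training/validation split
#'
#' Deterministic max-min selection on the autoscaled areas: start from
#' the two mutually farthest runs (Euclidean distance), then repeatedly
#' add the run whose minimum distance to the already-selected set is
#' largest; distance ties break towards the lowest run index. The
#' stratified variant applies the procedure within each class,
#' apportioning `nTrain` to the class sizes, so class proportions are
#' preserved.
#'
#' @param table a [LipidFeatureTable-class].
#' @param nTrain number of training runs, `2 <= nTrain < nRuns`
#'   (at least 2 per class when stratified).
#' @param stratified select within classes (default `TRUE`).
#' @return A list with integer run indices `train` (in selection order)
#'   and `validation`.
#' @examples
#' tab <- generateDataset(generatorConfig(seed = 3))
#' kennardStoneSplit(tab, nTrain = 18)
#' @export
kennardStoneSplit <- function(table, nTrain, stratified = TRUE) {
  X <- areaMatrix(table)
  n <- nrow(X)
  nTrain <- as.integer(nTrain)
  if (nTrain < 2L || nTrain >= n)
    stop("nTrain must satisfy 2 <= nTrain < nRuns")
  sds <- apply(X, 2, sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  D <- as.matrix(dist(Xs))
  if (!stratified) {
    train <- .ksGreedy(D, seq_len(n), nTrain)
  } else {
    y <- classCoding(table)
    n1 <- sum(y == 1)
    k1 <- round(nTrain * n1 / n)
    k0 <- nTrain - k1
    if (k1 < 2L || k0 < 2L)
      stop("stratified split needs at least 2 training runs per class")
    train <- c(.ksGreedy(D, which(y == 1), k1),
               .ksGreedy(D, which(y == -1), k0))
  }
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Kennard-Stone validation of PLS-DA at a fixed #LV
#'
#' A single deterministic split (default 3:1) by [kennardStoneSplit()],
#' PLS-DA fit on the training runs, diagnostics on the held-out runs.
#'
#' @inheritParams bootstrapValidation
#' @param stratified passed to [kennardStoneSplit()].
#' @param trainFraction fraction of runs selected for training
#'   (default 0.75).
#' @return A [ValidationReport-class] with a single repetition row.
#' @export
kennardStoneValidation <- function(table, nLV, stratified = TRUE,
                                   trainFraction = 0.75, autoscale = TRUE) {
  .assertTwoClass(table, min_per_class = 2L, what = "kennardStoneValidation")
  X <- areaMatrix(table)
  y <- classCoding(table)
  sp <- kennardStoneSplit(table, nTrain = round(trainFraction * length(y)),
                          stratified = stratified)
  a <- min(nLV, length(sp$train) - 1L)
  fit <- .fitPLSMat(X[sp$train, , drop = FALSE], y[sp$train], a, autoscale)
  yh <- .predPLSAllMat(fit, X[sp$validation, , drop = FALSE])[, fit$nLV]
  d <- diagnosticSet(y[sp$validation], yh)
  rows <- matrix(.diagVec(d), 1, length(.DIAG_COLS),
                 dimnames = list(NULL, .DIAG_COLS))
  .makeReport(if (stratified) "kennard_stone_stratified" else
                "kennard_stone", as.data.frame(rows),
              nLV = as.numeric(nLV), seed = NA_real_,
              extra = list(split = sp))
}

#' Permutation-test p-value
#'
#' `p = (1 + #(NMC_perm <= NMC)) / N`; its floor is `1/N`.
#'
#' @param count number of permuted models with NMC at or below the
#'   reference.
#' @param nPermutations N, the number of permutations.
#' @return numeric p-value.
#' @examples
#' permutationPValue(2, 30000)   # 1e-4
#' permutationPValue(0, 30000)   # 1/30000
#' @export
permutationPValue <- function(count, nPermutations) {
  stopifnot(count >= 0, nPermutations >= 1, count <= nPermutations)
  (1 + count) / nPermutations
}

#' Permutation test on the number of misclassifications
#'
#' Estimates the null distribution of the number of misclassified runs
#' (NMC) by refitting the PLS-DA classifier under random permutations
#' of the class labels: each permutation is evaluated by simple
#' stratified cross-validation (default 6-fold; `folds = n` gives
#' leave-one-out) at a fixed latent-variable count, and its pooled CV
#' predictions yield one NMC value. The observed (reference) NMC —
#' typically the rounded mean NMC of the double-cross-validation phase —
#' is compared against this distribution via [permutationPValue()].
#' For balanced classes the null NMC is centred near `n/2`, the mean of
#' a binomial(n, 1/2).
#'
#' @param table a [LipidFeatureTable-class].
#' @param nPermutations number of label permutations (default 30000).
#' @param nLV fixed latent-variable count.
#' @param referenceNMC observed NMC from the model's validation phase.
#' @param folds stratified CV fold count per permutation (default 6).
#' @param autoscale passed to the PLS fits.
#' @param seed integer RNG seed.
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(table, nPermutations = 30000, nLV, referenceNMC,
                            folds = 6, autoscale = TRUE, seed = 1L) {
  .assertTwoClass(table, min_per_class = 2L, what = "permutationTest")
  stopifnot(nPermutations >= 1, referenceNMC >= 0)
  X <- areaMatrix(table)
  y <- classCoding(table)
  n <- length(y)
  set.seed(seed)
  nmc <- integer(nPermutations)
  for (r in seq_len(nPermutations)) {
    yp <- sample(y)
    if (length(unique(yp)) < 2L)
      stop("constant permuted labels")     # impossible for two classes
    fold <- .stratifiedFolds(yp, folds)
    yhat <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      a <- min(nLV, sum(tr) - 1L)
      fit <- .fitPLSMat(X[tr, , drop = FALSE], yp[tr], a, autoscale)
      yhat[!tr] <- .predPLSAllMat(fit, X[!tr, , drop = FALSE])[, fit$nLV]
    }
    nmc[r] <- sum(ifelse(yhat > 0, 1, -1) != yp)
  }
  count <- sum(nmc <= referenceNMC)
  methods::new("PermutationResult", observedNMC = as.numeric(referenceNMC),
               nmcPerm = nmc, count = as.integer(count),
               pValue = permutationPValue(count, nPermutations),
               nPermutations = as.integer(nPermutations),
               nRuns = as.integer(n), seed = as.numeric(seed))
}

#' @describeIn PermutationResult-class compact display.
#' @param object a `PermutationResult`.
#' @export
setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(paste0("PermutationResult: N=%d, observed NMC=%g, ",
                     "#(NMC_P <= NMC)=%d, p=%.3g\n  H0 NMC mean=%.2f ",
                     "(n=%d runs)\n"),
              object@nPermutations, object@observedNMC, object@count,
              object@pValue, mean(object@nmcPerm), object@nRuns))
})
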