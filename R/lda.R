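# Matrix-level LDA core used by the resampling loops.
.fitLDAMat <- function(X, y, ridge = 1e-8) {
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == -1, , drop = FALSE])
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  S <- ((n1 - 1) * stats::cov(X[y == 1, , drop = FALSE]) +
        (n0 - 1) * stats::cov(X[y == -1, , drop = FALSE])) / (n1 + n0 - 2)
  p <- ncol(X)
  if (ridge > 0)
    S <- S + diag(ridge * sum(diag(S)) / p, p)
  w <- tryCatch(solve(S, m1 - m0), error = function(e)
    stop("pooled covariance is singular",
         if (ridge > 0) " even after ridge stabilisation" else
           "; consider a positive ridge"))
  list(m0 = m0, m1 = m1, S = S, w = as.numeric(w),
       threshold = sum(w * (m1 + m0)) / 2, variables = colnames(X),
       ridge = ridge)
}

.predLDAMat <- function(fit, X)
  as.vector(X[, fit$variables, drop = FALSE] %*% fit$w) - fit$threshold

#' Fit a two-class linear discriminant model
#'
#' Pooled-covariance LDA with equal priors. The discriminant direction
#' is `S^-1 (m_IRR - m_NI)` with `S` the pooled within-class covariance;
#' the decision threshold is the projected midpoint of the class means,
#' so in one dimension with equal variances the boundary is the
#' pooled-variance midpoint of the means. When `S` is near-singular
#' (e.g. collinear variables) a ridge `ridge * trace(S)/p` is added to
#' the diagonal; with `ridge = 0` a singular covariance is an error.
#'
#' @param table a prepared [LipidFeatureTable-class] (variables already
#'   capped and transformed, see [prepareLDAVariables()]); both classes
#'   with >= 2 runs.
#' @param ridge relative ridge term (default `1e-8`).
#' @return An [LDAModel-class].
#' @export
fitLDA <- function(table, ridge = 1e-8) {
  .assertTwoClass(table, min_per_class = 2L, what = "fitLDA")
  fit <- .fitLDAMat(areaMatrix(table), classCoding(table), ridge)
  methods::new("LDAModel", meanNI = fit$m0, meanIRR = fit$m1,
               pooledCov = fit$S, direction = fit$w,
               threshold = fit$threshold, variables = fit$variables,
               ridge = ridge, priors = c(NI = 0.5, IRR = 0.5))
}

#' Predict from a fitted LDA model
#'
#' @param model an [LDAModel-class].
#' @param table a [LipidFeatureTable-class] containing the model's
#'   variables.
#' @return A list with `y`, `yhat` (signed discriminant score,
#'   threshold already subtracted so 0 is the boundary) and `class`.
#' @export
predictLDA <- function(model, table) {
  stopifnot(methods::is(model, "LDAModel"))
  X <- areaMatrix(table)
  miss <- setdiff(model@variables, colnames(X))
  if (length(miss))
    stop("table lacks model variable(s): ", paste(miss, collapse = ", "))
  score <- .predLDAMat(list(variables = model@variables,
                            w = model@direction,
                            threshold = model@threshold), X)
  list(y = classCoding(table), yhat = score,
       class = factor(ifelse(score > 0, "IRR", "NI"), levels = .CLASSES))
}

# DiagnosticSet from LDA scores: class-based metrics only (the
# discriminant score is not on the +/-1 coding scale, so Q2/DQ2/RMSECV
# are not meaningful here)
.ldaDiagnostics <- function(y, score) {
  cm <- classificationMetrics(y, score)
  methods::new("DiagnosticSet", q2 = NA_real_, dq2 = NA_real_,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               accuracy = cm$accuracy,
               auroc = if (length(unique(y)) >= 2L) auroc(y, score)
                       else NA_real_,
               rmsecv = NA_real_, trmsecv = NA_real_, iEff = NA_real_,
               nmc = cm$nmc, n = length(y))
}

#' Repeated stratified cross-validation of the LDA branch
#'
#' Each repetition draws a stratified random train/validation split
#' (default 3:1, preserving class proportions), fits the LDA on the
#' training part and scores the validation part; sensitivity,
#' specificity, accuracy, AUROC and NMC are averaged over repetitions.
#'
#' @param table a prepared [LipidFeatureTable-class].
#' @param repetitions number of repetitions (default 10000).
#' @param trainFraction fraction of each class used for training
#'   (default 0.75).
#' @param ridge passed to [fitLDA()].
#' @param seed integer RNG seed.
#' @return A [ValidationReport-class].
#' @export
crossvalidateLDA <- function(table, repetitions = 10000, trainFraction = 0.75,
                             ridge = 1e-8, seed = 1L) {
  .assertTwoClass(table, min_per_class = 3L, what = "crossvalidateLDA")
  set.seed(seed)
  X <- areaMatrix(table)
  y <- classCoding(table)
  idx1 <- which(y == 1); idx0 <- which(y == -1)
  k1 <- round(trainFraction * length(idx1))
  k0 <- round(trainFraction * length(idx0))
  if (k1 < 2L || k0 < 2L || k1 >= length(idx1) || k0 >= length(idx0))
    stop("trainFraction leaves too few runs for training or validation")
  rows <- matrix(NA_real_, repetitions, length(.DIAG_COLS),
                 dimnames = list(NULL, .DIAG_COLS))
  for (r in seq_len(repetitions)) {
    tr <- c(sample(idx1, k1), sample(idx0, k0))
    fit <- .fitLDAMat(X[tr, , drop = FALSE], y[tr], ridge)
    sc <- .predLDAMat(fit, X[-tr, , drop = FALSE])
    rows[r, ] <- .diagVec(.ldaDiagnostics(y[-tr], sc))
  }
  .makeReport("lda_cv", as.data.frame(rows), nLV = NA_real_, seed = seed)
}

#' @describeIn LDAModel-class compact display.
#' @param object an `LDAModel`.
#' @export
setMethod("show", "LDAModel", function(object) {
  cat("LDAModel:", length(object@variables), "variable(s), equal priors,",
      "ridge", format(object@ridge), "\n")
})
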