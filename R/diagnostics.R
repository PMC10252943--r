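#' Classification metrics for a two-class coding
#'
#' The class coding used throughout is `IRR` = +1 (positive class) and
#' `NI` = -1; a continuous prediction classifies as `IRR` when strictly
#' greater than 0 (a prediction exactly at the threshold goes to `NI`).
#'
#' @param y numeric reference in `{-1, +1}`, both classes present.
#' @param yhat numeric continuous predictions, same length.
#' @return A list with `sensitivity` (= TP/(TP+FN)), `specificity`
#'   (= TN/(TN+FP)), `accuracy` and `nmc` (number of misclassified
#'   runs). Sensitivity (specificity) is `NA` if no positive (negative)
#'   reference is present — only possible when called on partial
#'   validation sets such as bootstrap out-of-bag draws.
#' @examples
#' classificationMetrics(c(-1, -1, 1, 1), c(-2, 0.5, 1, 2))
#' @export
classificationMetrics <- function(y, yhat) {
  .checkCoding(y, yhat, require_both = FALSE)
  pred <- ifelse(yhat > 0, 1, -1)
  tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == -1)
  tn <- sum(y == -1 & pred == -1); fp <- sum(y == -1 & pred == 1)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(y),
       nmc = fn + fp)
}

.checkCoding <- function(y, yhat, require_both = TRUE) {
  if (length(y) != length(yhat))
    stop("y and yhat must have the same length")
  if (!all(y %in% c(-1, 1)))
    stop("y must be coded -1 (NI) / +1 (IRR)")
  if (require_both && length(unique(y)) < 2L)
    stop("both classes must be present in y")
  invisible(TRUE)
}

#' Cross-validated explained deviance Q2 and its discriminant variant DQ2
#'
#' `q2()` is `1 - PRESS/TSS` with `PRESS = sum((y - yhat)^2)` and
#' `TSS = sum((y - mean(y))^2)`. `dq2()` replaces PRESS by `PRESS_D`,
#' which counts a residual only when the prediction falls short of its
#' class target: class -1 runs with `yhat > -1` and class +1 runs with
#' `yhat < +1`. A prediction beyond its target (e.g. 1.3 for class +1)
#' discriminates perfectly and contributes nothing, so `dq2 >= q2`
#' always.
#'
#' @inheritParams classificationMetrics
#' @return numeric scalar (unbounded below, at most 1).
#' @examples
#' y <- c(-1, -1, 1, 1)
#' q2(y, c(-0.5, -1.5, 0.5, 1.5))   # 0.75
#' dq2(y, c(-0.5, -1.5, 0.5, 1.5))  # 0.875
#' @export
q2 <- function(y, yhat) {
  .checkCoding(y, yhat)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("y is constant; Q2 undefined")
  1 - sum((y - yhat)^2) / tss
}

#' @rdname q2
#' @export
dq2 <- function(y, yhat) {
  .checkCoding(y, yhat)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("y is constant; DQ2 undefined")
  keep <- (y == -1 & yhat > -1) | (y == 1 & yhat < 1)
  1 - sum((y[keep] - yhat[keep])^2) / tss
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs in which the positive run's
#' prediction exceeds the negative run's, ties counting 0.5; computed
#' from ranks.
#'
#' @inheritParams classificationMetrics
#' @return numeric in `[0, 1]`.
#' @export
auroc <- function(y, yhat) {
  .checkCoding(y, yhat)
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  r <- rank(yhat)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root-mean-squared error of cross-validation
#'
#' `sqrt(PRESS / n)` over (cross-)validation predictions.
#'
#' @inheritParams classificationMetrics
#' @return numeric scalar, >= 0.
#' @export
rmsecv <- function(y, yhat) {
  .checkCoding(y, yhat, require_both = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Rescale an RMSECV onto \[0, 1\] over a scanned range
#'
#' `tRMSECV = (max - x)/(max - min) * (min / x)`: 1 at the scan minimum,
#' 0 at the scan maximum, monotonically non-increasing in between. The
#' range is the RMSECV values seen over a latent-variable scan, the only
#' context in which a min and max coexist. Degenerate `max == min`
#' returns 1.
#'
#' @param x RMSECV to rescale, in `[min, max]`, > 0.
#' @param min,max scan extremes.
#' @return numeric in `[0, 1]`.
#' @examples
#' trmsecv(0.3, 0.1, 0.5)  # 0.1667
#' @export
trmsecv <- function(x, min, max) {
  if (min > max) stop("min must be <= max")
  if (x < min - 1e-12 || x > max + 1e-12)
    stop("x must lie within [min, max]")
  if (max == min || x <= min) return(1)   # both factors are 1 at the minimum
  if (x <= 0) stop("x must be > 0")
  (max - x) / (max - min) * (min / x)
}

#' Efficiency index
#'
#' Sum of the seven inner-validation statistics
#' `Q2 + DQ2 + accuracy + sensitivity + specificity + AUROC + tRMSECV`;
#' at most 7 (perfection), unbounded below. Used to pick the
#' latent-variable count in double cross-validation.
#'
#' @param d a [DiagnosticSet-class] with all seven components computed
#'   on the same inner-validation predictions.
#' @return numeric scalar.
#' @export
iEff <- function(d) {
  stopifnot(methods::is(d, "DiagnosticSet"))
  comps <- c(d@q2, d@dq2, d@accuracy, d@sensitivity, d@specificity,
             d@auroc, d@trmsecv)
  if (anyNA(comps))
    stop("all seven components must be available to compute the efficiency index")
  sum(comps)
}

#' Assemble a DiagnosticSet from validation predictions
#'
#' Computes every scalar diagnostic from a reference coding and
#' continuous predictions. `tRMSECV` (and hence the efficiency index)
#' requires the RMSECV range of the enclosing latent-variable scan; both
#' are `NA` when `rmsecvRange` is omitted.
#'
#' @inheritParams classificationMetrics
#' @param rmsecvRange optional numeric length-2 `c(min, max)` of the
#'   RMSECV scan.
#' @return A [DiagnosticSet-class].
#' @examples
#' diagnosticSet(c(-1, -1, 1, 1), c(-0.5, -1.5, 0.5, 1.5))
#' @export
diagnosticSet <- function(y, yhat, rmsecvRange = NULL) {
  cm <- classificationMetrics(y, yhat)
  both <- length(unique(y)) >= 2L
  r <- rmsecv(y, yhat)
  tr <- if (is.null(rmsecvRange)) NA_real_ else
    trmsecv(r, rmsecvRange[1], rmsecvRange[2])
  d <- methods::new("DiagnosticSet",
    q2 = if (both) q2(y, yhat) else NA_real_,
    dq2 = if (both) dq2(y, yhat) else NA_real_,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    accuracy = cm$accuracy,
    auroc = if (both) auroc(y, yhat) else NA_real_,
    rmsecv = r, trmsecv = tr, iEff = NA_real_,
    nmc = cm$nmc, n = length(y))
  if (!is.na(tr)) d@iEff <- iEff(d)
  d
}

#' @describeIn DiagnosticSet-class one-line display.
#' @param object a `DiagnosticSet`.
#' @export
setMethod("show", "DiagnosticSet", function(object) {
  cat(sprintf(paste0("DiagnosticSet (n=%d): Q2=%.3f DQ2=%.3f acc=%.3f ",
                     "sens=%.3f spec=%.3f AUROC=%.3f RMSECV=%.3f NMC=%d\n"),
              object@n, object@q2, object@dq2, object@accuracy,
              object@sensitivity, object@specificity, object@auroc,
              object@rmsecv, as.integer(object@nmc)))
})

#' @describeIn DiagnosticSet-class coerce to a one-row data.frame.
#' @param x a `DiagnosticSet`.
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.DiagnosticSet <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(q2 = x@q2, dq2 = x@dq2, sensitivity = x@sensitivity,
             specificity = x@specificity, accuracy = x@accuracy,
             auroc = x@auroc, rmsecv = x@rmsecv, trmsecv = x@trmsecv,
             i_eff = x@iEff, nmc = x@nmc, n = x@n)
}
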