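# Matrix-level NIPALS PLS1 core. The exported S4 layer wraps these;
# the resampling protocols call them directly to avoid container
# overhead in their inner loops.
.fitPLSMat <- function(X, y, nLV, autoscale = TRUE, quiet = FALSE) {
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(nrow(X) - 1L, ncol(X)))
    stop("nLV must be in [1, min(nRuns - 1, nLipids)]")
  xc <- colMeans(X)
  Xc <- sweep(X, 2, xc)
  sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  keep <- sds > 0
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    if (!quiet)
      message("dropping ", length(dropped), " zero-variance lipid(s)")
    Xc <- Xc[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  xs <- if (autoscale) sds else rep(1, ncol(Xc))
  Xc <- sweep(Xc, 2, xs, "/")
  ym <- mean(y)
  yd <- y - ym

  p <- ncol(Xc)
  W <- P <- matrix(0, p, nLV)
  Tm <- matrix(0, nrow(Xc), nLV)
  q <- ssy <- numeric(nLV)
  Xd <- Xc
  for (a in seq_len(nLV)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {                  # predictive variation exhausted
      nLV <- a - 1L
      if (nLV < 1L) stop("no predictive variation in X")
      W <- W[, seq_len(nLV), drop = FALSE]
      P <- P[, seq_len(nLV), drop = FALSE]
      Tm <- Tm[, seq_len(nLV), drop = FALSE]
      q <- q[seq_len(nLV)]; ssy <- ssy[seq_len(nLV)]
      break
    }
    w <- w / nw
    t <- as.vector(Xd %*% w)
    tt <- sum(t^2)
    pl <- as.vector(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t
    q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  list(nLV = nLV, W = W, P = P, q = q, ssy = ssy, Tm = Tm,
       xc = xc[keep], xs = xs, ym = ym,
       lipids = colnames(X)[keep], dropped = dropped)
}

# cumulative predictions for 1..fit$nLV components; X raw areas with the
# model's lipid columns present; returns n x nLV matrix
.predPLSAllMat <- function(fit, X) {
  Xd <- sweep(sweep(X[, fit$lipids, drop = FALSE], 2, fit$xc), 2,
              fit$xs, "/")
  n <- nrow(Xd)
  out <- matrix(0, n, fit$nLV)
  acc <- rep(fit$ym, n)
  for (a in seq_len(fit$nLV)) {
    t <- as.vector(Xd %*% fit$W[, a])
    acc <- acc + fit$q[a] * t
    out[, a] <- acc
    Xd <- Xd - tcrossprod(t, fit$P[, a])
  }
  out
}

.plsModelFromFit <- function(fit, autoscale) {
  methods::new("PLSModel", nLV = fit$nLV, weights = fit$W,
               loadings = fit$P, yLoadings = fit$q, scores = fit$Tm,
               ssy = fit$ssy, xCenter = fit$xc, xScale = fit$xs,
               yMean = fit$ym, lipids = fit$lipids, autoscale = autoscale,
               dropped = fit$dropped)
}

.fitFromPLSModel <- function(model) {
  list(nLV = model@nLV, W = model@weights, P = model@loadings,
       q = model@yLoadings, ssy = model@ssy, Tm = model@scores,
       xc = model@xCenter, xs = model@xScale, ym = model@yMean,
       lipids = model@lipids, dropped = model@dropped)
}

#' Fit a two-class PLS-DA model
#'
#' NIPALS PLS1 regression of the class coding (`IRR` = +1, `NI` = -1)
#' on the area matrix. X is mean-centred and, with `autoscale = TRUE`
#' (the default), scaled to unit variance; the response is centred.
#' Lipids with zero training variance are dropped (recorded in the
#' model). The fit is deterministic and invariant to run order.
#'
#' PLS-DA handles more predictors than runs, the normal situation in
#' untargeted lipidomics; with `nLV = rank(X)` the predictions coincide
#' with ordinary least squares.
#'
#' @param table a [LipidFeatureTable-class] with both classes present.
#' @param nLV number of latent variables, at most
#'   `min(nRuns - 1, nLipids)`.
#' @param autoscale scale lipids to unit variance (default `TRUE`);
#'   heterogeneous lipid magnitudes otherwise let the most abundant
#'   subclasses dominate the covariance.
#' @return A [PLSModel-class].
#' @examples
#' tab <- generateDataset(generatorConfig(seed = 1))
#' m <- fitPLS(ionModeView(tab, "negative"), nLV = 3)
#' head(sort(vipScores(m), decreasing = TRUE))
#' @export
fitPLS <- function(table, nLV, autoscale = TRUE) {
  .assertTwoClass(table, what = "fitPLS")
  fit <- .fitPLSMat(areaMatrix(table), classCoding(table), nLV,
                    autoscale = autoscale, quiet = FALSE)
  .plsModelFromFit(fit, autoscale)
}

#' Predict from a fitted PLS-DA model
#'
#' @param model a [PLSModel-class].
#' @param table a [LipidFeatureTable-class] whose lipids include the
#'   model's.
#' @param nLV number of components to use (default: the model's).
#' @return A list with `y` (reference coding of `table`), `yhat`
#'   (continuous predictions) and `class` (hard labels by the sign
#'   threshold at 0, ties to `NI`).
#' @export
predictPLS <- function(model, table, nLV = model@nLV) {
  stopifnot(methods::is(model, "PLSModel"))
  X <- areaMatrix(table)
  miss <- setdiff(model@lipids, colnames(X))
  if (length(miss))
    stop("table lacks model lipid(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > model@nLV)
    stop("nLV must be in [1, ", model@nLV, "]")
  yhat <- .predPLSAllMat(.fitFromPLSModel(model), X)[, nLV]
  list(y = classCoding(table), yhat = yhat,
       class = factor(ifelse(yhat > 0, "IRR", "NI"), levels = .CLASSES))
}

#' Variable importance in projection
#'
#' Standard VIP with cumulative explained-response weighting:
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` (weight
#' vectors are unit length). The mean squared VIP equals 1, so 1 is the
#' conventional importance cut-off.
#'
#' @param model a fitted [PLSModel-class].
#' @return named numeric vector of VIP scores (dropped zero-variance
#'   lipids are absent).
#' @export
vipScores <- function(model) {
  stopifnot(methods::is(model, "PLSModel"))
  if (model@nLV < 1L) stop("model is not fitted")
  swk <- model@weights^2 %*% model@ssy
  setNames(sqrt(length(model@lipids) * as.vector(swk) / sum(model@ssy)),
           model@lipids)
}

#' Serialize a PLS model to a portable JSON file
#'
#' @param model a [PLSModel-class].
#' @param path output (input) file path.
#' @return `writePLSModel()` invisibly `path`; `readPLSModel()` the
#'   restored [PLSModel-class] (training scores are not serialized).
#' @export
writePLSModel <- function(model, path) {
  stopifnot(methods::is(model, "PLSModel"))
  obj <- list(nLV = model@nLV, weights = model@weights,
              loadings = model@loadings, yLoadings = model@yLoadings,
              ssy = model@ssy, xCenter = model@xCenter,
              xScale = model@xScale, yMean = model@yMean,
              lipids = model@lipids, autoscale = model@autoscale,
              dropped = model@dropped)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("PLSModel", nLV = as.integer(o$nLV),
               weights = as.matrix(o$weights),
               loadings = as.matrix(o$loadings),
               yLoadings = as.numeric(o$yLoadings),
               scores = matrix(numeric(0), 0, 0),
               ssy = as.numeric(o$ssy), xCenter = as.numeric(o$xCenter),
               xScale = as.numeric(o$xScale), yMean = as.numeric(o$yMean),
               lipids = as.character(o$lipids), autoscale = o$autoscale,
               dropped = as.character(o$dropped))
}

#' @describeIn PLSModel-class compact display.
#' @param object a `PLSModel`.
#' @export
setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@nLV, "latent variable(s),",
      length(object@lipids), "lipids,",
      if (object@autoscale) "autoscaled" else "centred only", "\n")
})
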