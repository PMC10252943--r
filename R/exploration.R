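#' Unsupervised PCA with outlier distances
#'
#' Deterministic SVD-based PCA on the autoscaled area matrix
#' (zero-variance lipids are dropped with a message). The sign of each
#' component is fixed so that its largest-magnitude loading is
#' positive. For the chosen component count the per-run orthogonal
#' distance (residual sum of squares off the score plane) and Hotelling
#' T2 distance (Mahalanobis distance in score space) are computed and
#' normalised by their training means, so each averages 1 over the
#' runs.
#'
#' @param table a [LipidFeatureTable-class].
#' @param nComponents components retained for the distance computation
#'   (default 2, the pair usually inspected in score plots); at most
#'   `min(nRuns - 1, nLipids)`.
#' @return A [PCAResult-class].
#' @examples
#' tab <- generateDataset(generatorConfig(seed = 5))
#' pca <- pcaFit(tab)
#' head(pca@explainedVariance)
#' @export
pcaFit <- function(table, nComponents = 2) {
  X <- areaMatrix(table)
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) stop("constant table: PCA undefined")
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " zero-variance lipid(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  nComponents <- as.integer(nComponents)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (nComponents < 1L || nComponents > kmax)
    stop("nComponents must be in [1, min(nRuns - 1, nLipids)]")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  sco <- sweep(pc$x, 2, flip, "*")
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)

  k <- nComponents
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  resid <- Xs - sco[, seq_len(k), drop = FALSE] %*%
    t(rot[, seq_len(k), drop = FALSE])
  od <- rowSums(resid^2)
  lam <- pc$sdev[seq_len(k)]^2
  t2 <- rowSums(sweep(sco[, seq_len(k), drop = FALSE]^2, 2, lam, "/"))
  od <- if (mean(od) > 0) od / mean(od) else od
  t2 <- t2 / mean(t2)
  methods::new("PCAResult", scores = sco, loadings = rot,
               explainedVariance = ev, nComponents = k,
               od = od, t2 = t2, center = ctr, scale = scl,
               runs = rownames(X))
}

#' Screen runs for outliers by normalised distances
#'
#' Compares each run's normalised orthogonal and Hotelling T2 distances
#' to critical limits at significance `alpha`, and flags runs exceeding
#' either. Limits come from moment-matched scaled chi-squared
#' approximations (the convention of the chemometrics SIMCA family): a
#' distance with mean `m` and variance `v` is treated as
#' `(m/h) * chi2_h` with `h = 2 m^2 / v` degrees of freedom, giving the
#' limit `(m/h) * qchisq(1 - alpha, h)`. Each run is judged against
#' moments estimated from the other runs (leave-one-out), so a single
#' gross outlier cannot inflate its own limit and mask itself.
#'
#' @param pca a [PCAResult-class].
#' @param alpha significance level in (0, 1) (default 0.01).
#' @return A list: logical `flags` per run, per-run critical limits
#'   `odLimit` and `t2Limit` (leave-one-out), `alpha`, and the
#'   normalised distances `od`, `t2`.
#' @export
outlierScreen <- function(pca, alpha = 0.01) {
  stopifnot(methods::is(pca, "PCAResult"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  lims <- function(d) {
    vapply(seq_along(d), function(i) {
      m <- mean(d[-i]); v <- var(d[-i])
      if (!is.finite(v) || v < 1e-12 || m <= 0) return(Inf)
      h <- 2 * m^2 / v
      m * qchisq(1 - alpha, h) / h
    }, numeric(1))
  }
  odl <- lims(pca@od)
  t2l <- lims(pca@t2)
  flags <- pca@od > odl | pca@t2 > t2l
  names(flags) <- pca@runs
  list(flags = flags, odLimit = odl, t2Limit = t2l, alpha = alpha,
       od = pca@od, t2 = pca@t2)
}

#' @describeIn PCAResult-class compact display.
#' @param object a `PCAResult`.
#' @export
setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", length(object@runs), "runs,",
      nrow(object@loadings), "lipids,",
      object@nComponents, "component(s) for distances\n")
  cat("  explained variance (%):",
      paste(round(utils::head(object@explainedVariance, 4), 1),
            collapse = ", "), "...\n")
})
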