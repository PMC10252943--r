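# shared in-code fixtures; all randomness is seeded locally

# small two-class table with `n_inf` informative lipids (class shift
# `delta` SDs) and `n_noise` pure-noise lipids
makeToyTable <- function(nPerClass = 6, n_inf = 2, n_noise = 3,
                         delta = 4, seed = 42, base = 100, sd = 5) {
  set.seed(seed)
  n <- 2 * nPerClass
  p <- n_inf + n_noise
  X <- matrix(rnorm(n * p, base, sd), n, p)
  if (n_inf > 0)
    X[seq_len(nPerClass) + nPerClass, seq_len(n_inf)] <-
      X[seq_len(nPerClass) + nPerClass, seq_len(n_inf)] + delta * sd
  colnames(X) <- c(sprintf("PE (inf_%d)", seq_len(n_inf)),
                   sprintf("PC (noise_%d)", seq_len(n_noise)))[seq_len(p)]
  X <- pmax(X, 1e-3)
  LipidFeatureTable(X, classes = rep(c("NI", "IRR"), each = nPerClass),
                    lipidData = data.frame(
                      subclass = c(rep("PE", n_inf), rep("PC", n_noise)),
                      ion_mode = "negative",
                      row.names = colnames(X)))
}

# unstructured positive random table (no class effect)
makeRandomTable <- function(n = 8, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p, 50, 150), n, p,
              dimnames = list(NULL, sprintf("PI (r_%d)", seq_len(p))))
  LipidFeatureTable(X, classes = rep(c("NI", "IRR"), length.out = n))
}

# independent all-pairs AUROC oracle
aurocOracle <- function(y, yhat) {
  pos <- yhat[y == 1]; neg <- yhat[y == -1]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# independent stepwise Kennard-Stone oracle: enumerates every candidate
# at every step of the greedy max-min criterion
ksOracle <- function(X, k) {
  Xs <- scale(X)
  D <- as.matrix(dist(Xs))
  n <- nrow(D)
  best <- c(Inf, Inf); mx <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > mx) { mx <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(c) min(D[c, sel]), numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

negativeLDAMarkerIds <- function(catalog = loadMarkerCatalog()) {
  catalog$lipid_id[catalog$ion_mode == "negative" &
    vapply(catalog$marker_models, function(m) "LDA" %in% m, logical(1))]
}
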