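#' Volcano-plot statistics: per-lipid ANOVA p-value and fold change
#'
#' For every lipid, a two-group one-way ANOVA F-test (identical to the
#' squared equal-variance t-test) of `IRR` vs `NI`, and the log2 fold
#' change of the class means (`IRR` over `NI`). A lipid with zero
#' within-class variance in both classes gets `p = 0` when the means
#' differ and `p = 1` when they are identical (exact-equality rule,
#' flagged by a message). The volcano selection threshold `p <= 0.05`
#' corresponds to `-log10 p >= 1.3`.
#'
#' @param table a [LipidFeatureTable-class] with >= 2 runs per class.
#' @param method `"anova"` (classic equal-variance F-test, default) or
#'   `"welch"` (Welch t-test, unequal variances).
#' @return A `data.frame` (one row per lipid): `lipid`, `p_value`,
#'   `neg_log10_p`, `log2_fc`, plus empty columns `vip`,
#'   `selected_plsda`, `selected_lda`, `log_transform` filled by the
#'   downstream selection steps.
#' @examples
#' tab <- generateDataset(generatorConfig(seed = 1))
#' sel <- volcanoStats(ionModeView(tab, "negative"))
#' head(sel[order(sel$p_value), ])
#' @export
volcanoStats <- function(table, method = c("anova", "welch")) {
  method <- match.arg(method)
  .assertTwoClass(table, min_per_class = 2L, what = "volcanoStats")
  X <- areaMatrix(table)
  y <- classCoding(table)
  X1 <- X[y == 1, , drop = FALSE]; X0 <- X[y == -1, , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- apply(X1, 2, var); v0 <- apply(X0, 2, var)
  if (method == "anova") {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tstat2 <- (m1 - m0)^2 / (sp2 * (1 / n1 + 1 / n0))
    p <- pf(tstat2, 1, n1 + n0 - 2, lower.tail = FALSE)
  } else {
    se2 <- v1 / n1 + v0 / n0
    tstat2 <- (m1 - m0)^2 / se2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- pf(tstat2, 1, df, lower.tail = FALSE)
  }
  degen <- v1 == 0 & v0 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] != m0[degen], 0, 1)
    message(sum(degen), " lipid(s) with zero within-class variance; ",
            "p set by the exact-equality rule")
  }
  data.frame(lipid = colnames(X), p_value = p, neg_log10_p = -log10(p),
             log2_fc = log2(m1 / m0), vip = NA_real_,
             selected_plsda = NA, selected_lda = NA, log_transform = NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag PLS-DA markers by volcano p-value and VIP score
#'
#' A lipid is selected when its ANOVA `p <= pThreshold` (default 0.05)
#' and its VIP score from the fitted PLS-DA model is `>= vipThreshold`
#' (default 1, the mean-squared-VIP level). Lipids dropped from the
#' model (zero variance) are never selected.
#'
#' @param table the [LipidFeatureTable-class] both inputs were computed
#'   on.
#' @param model a [PLSModel-class] fitted on `table`.
#' @param sel a selection `data.frame` from [volcanoStats()] on `table`.
#' @param pThreshold,vipThreshold selection cut-offs.
#' @return `sel` with `vip` filled and `selected_plsda` set.
#' @export
selectPLSDAMarkers <- function(table, model, sel, pThreshold = 0.05,
                               vipThreshold = 1) {
  if (!setequal(sel$lipid, rownames(table)))
    stop("selection table and feature table cover different lipid sets")
  if (length(setdiff(model@lipids, sel$lipid)))
    stop("model and selection table cover different lipid sets")
  vip <- vipScores(model)
  sel$vip <- unname(vip[sel$lipid])
  sel$selected_plsda <- !is.na(sel$vip) & sel$p_value <= pThreshold &
    sel$vip >= vipThreshold
  sel
}

#' Prepare the LDA variable block
#'
#' Keeps the volcano-selected lipids (`p <= pThreshold`), ranked by
#' ascending p-value and capped (when `cap = TRUE`) at the per-class
#' object count — LDA requires no more variables than objects per
#' category. Each retained lipid is then tested for normality per class
#' with the Lilliefors test at `alpha`; lipids failing in either class
#' are natural-log transformed (areas are positive by construction).
#'
#' @param table a [LipidFeatureTable-class].
#' @param sel a selection `data.frame` from [volcanoStats()].
#' @param alpha Lilliefors significance level (default 0.05).
#' @param pThreshold volcano inclusion threshold (default 0.05).
#' @param cap apply the per-class object-count cap (default `TRUE`).
#' @return A list: `table` (the transformed sub-table), `transforms`
#'   (`data.frame` with per-lipid Lilliefors p-values per class and the
#'   log-transform flag), and `selection` (`sel` with `selected_lda`
#'   and `log_transform` set).
#' @export
prepareLDAVariables <- function(table, sel, alpha = 0.05, pThreshold = 0.05,
                                cap = TRUE) {
  .assertTwoClass(table, min_per_class = 2L, what = "prepareLDAVariables")
  if (!setequal(sel$lipid, rownames(table)))
    stop("selection table and feature table cover different lipid sets")
  y <- classCoding(table)
  n_cap <- min(sum(y == 1), sum(y == -1))
  cand <- sel[sel$p_value <= pThreshold, ]
  cand <- cand[order(cand$p_value, cand$lipid), ]
  if (cap && nrow(cand) > n_cap)
    cand <- cand[seq_len(n_cap), ]
  if (!nrow(cand)) stop("no lipids pass the volcano threshold")
  keep <- cand$lipid
  X <- areaMatrix(table)[, keep, drop = FALSE]
  lil <- function(v) {
    if (length(v) < 5L || sd(v) == 0) return(NA_real_)
    nortest::lillie.test(v)$p.value
  }
  p_ni <- apply(X[y == -1, , drop = FALSE], 2, lil)
  p_irr <- apply(X[y == 1, , drop = FALSE], 2, lil)
  fails <- (!is.na(p_ni) & p_ni < alpha) | (!is.na(p_irr) & p_irr < alpha)
  if (any(X[, fails, drop = FALSE] <= 0))
    stop("non-positive area under log transformation")
  Xt <- X
  Xt[, fails] <- log(X[, fails, drop = FALSE])
  rm <- runMeta(table)
  sub <- LipidFeatureTable(Xt, classes = rm$class, cheese = rm$cheese,
                           replicate = rm$replicate,
                           lipidData = lipidMeta(table)[keep, , drop = FALSE],
                           transformed = any(fails))
  sel$selected_lda <- sel$lipid %in% keep
  sel$log_transform <- NA
  sel$log_transform[match(keep, sel$lipid)] <- unname(fails)
  list(table = sub,
       transforms = data.frame(lipid = keep, p_lilliefors_NI = p_ni,
                               p_lilliefors_IRR = p_irr,
                               log_transformed = fails, row.names = NULL),
       selection = sel)
}

#' Volcano plot of the per-lipid screening statistics
#'
#' Thin optional layer over ggplot2: `-log10 p` against `log2` fold
#' change, selection thresholds drawn as dashed lines.
#'
#' @param sel a selection `data.frame` from [volcanoStats()].
#' @param pThreshold volcano threshold drawn (default 0.05).
#' @return A ggplot object.
#' @export
plotVolcano <- function(sel, pThreshold = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotVolcano requires the ggplot2 package")
  df <- data.frame(log2_fc = sel$log2_fc, neg_log10_p = sel$neg_log10_p,
                   significant = sel$p_value <= pThreshold)
  ggplot2::ggplot(df, ggplot2::aes(x = log2_fc, y = neg_log10_p,
                                   colour = significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(pThreshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (IRR / NI)",
                  y = "-log10 p (ANOVA)", colour = "p <= threshold")
}

utils::globalVariables(c("log2_fc", "neg_log10_p", "significant"))
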