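#' Assemble a pipeline configuration
#'
#' Bundles every tunable of the full analysis: the input (a CSV path or
#' a generator configuration), the ion-mode filter, the selection
#' thresholds, the protocol sizes and the master seed. All protocol
#' seeds are derived from the master seed as fixed offsets, so a
#' configuration determines every number the pipeline produces.
#'
#' @param input path to a feature-table CSV, or `NULL` to simulate.
#' @param generator a [generatorConfig()] used when `input` is `NULL`
#'   (its seed is overridden by `seed + 1`).
#' @param ionMode `"negative"` (default) or `"positive"`.
#' @param pThreshold,vipThreshold volcano/VIP selection cut-offs
#'   (defaults 0.05 and 1).
#' @param alphaOutlier PCA outlier-screen significance (default 0.01).
#' @param alphaLilliefors LDA normality-gate significance (default
#'   0.05).
#' @param maxLV latent-variable scan ceiling (default 10).
#' @param dcvRepetitions double-CV repetitions (default 200).
#' @param foldsOuter,foldsInner double-CV fold counts (defaults 4, 5).
#' @param protocolIterations bootstrap/subsampling/LDA-CV iterations
#'   (default 10000).
#' @param nPermutations permutation-test size (default 30000).
#' @param trainFraction train share of the 3:1 protocols (default
#'   0.75).
#' @param seed master seed.
#' @param outputDir directory for the report bundle.
#' @return A named list (validated).
#' @export
pipelineConfig <- function(input = NULL, generator = generatorConfig(),
                           ionMode = c("negative", "positive"),
                           pThreshold = 0.05, vipThreshold = 1,
                           alphaOutlier = 0.01, alphaLilliefors = 0.05,
                           maxLV = 10, dcvRepetitions = 200,
                           foldsOuter = 4, foldsInner = 5,
                           protocolIterations = 10000,
                           nPermutations = 30000, trainFraction = 0.75,
                           seed = 1L, outputDir = tempfile("lipidisc_")) {
  stopifnot(pThreshold > 0, pThreshold < 1, vipThreshold >= 0,
            alphaOutlier > 0, alphaOutlier < 1,
            alphaLilliefors > 0, alphaLilliefors < 1,
            maxLV >= 1, dcvRepetitions >= 1, protocolIterations >= 1,
            nPermutations >= 1, trainFraction > 0, trainFraction < 1)
  list(input = input, generator = generator,
       ionMode = match.arg(ionMode), pThreshold = pThreshold,
       vipThreshold = vipThreshold, alphaOutlier = alphaOutlier,
       alphaLilliefors = alphaLilliefors, maxLV = maxLV,
       dcvRepetitions = dcvRepetitions, foldsOuter = foldsOuter,
       foldsInner = foldsInner, protocolIterations = protocolIterations,
       nPermutations = nPermutations, trainFraction = trainFraction,
       seed = as.integer(seed), outputDir = outputDir)
}

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full discrimination analysis
#'
#' Executes, in order: data input (read or simulate), PCA exploration
#' with outlier screening, volcano/VIP marker selection, PLS-DA double
#' cross-validation, the fixed-#LV protocols (bootstrap, stratified
#' subsampling, stratified and plain Kennard-Stone), the LDA branch
#' (variable preparation + repeated stratified CV), and the PLS-DA
#' permutation test referenced to the rounded mean double-CV NMC.
#' Writes to `config$outputDir`: the selection table
#' (`selection.csv`), a protocol-by-statistic diagnostics table
#' (`diagnostics.csv`), per-protocol per-repetition tables, the
#' permutation summary and histogram, the outlier screen, and the
#' resolved configuration (`config.json`) — re-running from which
#' reproduces the bundle exactly.
#'
#' @param config a [pipelineConfig()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with every stage result (`table`, `pca`,
#'   `outliers`, `selection`, `plsModel`, `doubleCV`, `bootstrap`,
#'   `subsampling`, `kennardStone`, `kennardStonePlain`, `lda`,
#'   `permutation`, `outputDir`).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(seed = 7, dcvRepetitions = 5,
#'                       protocolIterations = 50, nPermutations = 50)
#' res <- runPipeline(cfg, quiet = TRUE)
#' summary(res$doubleCV)
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else message
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  say("stage input")
  tab <- .stageTry("input", {
    if (is.null(config$input)) {
      gen <- config$generator
      gen@seed <- config$seed + 1L
      generateDataset(gen)
    } else readFeatureTable(config$input)
  })
  view <- .stageTry("input", ionModeView(tab, config$ionMode))

  say("stage exploration")
  pca <- .stageTry("exploration", pcaFit(view))
  outl <- .stageTry("exploration", outlierScreen(pca, config$alphaOutlier))

  say("stage selection")
  sel <- .stageTry("selection", {
    set.seed(config$seed + 2L)
    m <- fitPLS(view, nLV = min(config$maxLV, nRuns(view) - 1L))
    selectPLSDAMarkers(view, m, volcanoStats(view),
                       pThreshold = config$pThreshold,
                       vipThreshold = config$vipThreshold)
  })

  say("stage double cross-validation")
  dcv <- .stageTry("double_cv",
    doubleCrossValidation(view, maxLV = config$maxLV,
                          repetitions = config$dcvRepetitions,
                          foldsOuter = config$foldsOuter,
                          foldsInner = config$foldsInner,
                          seed = config$seed + 3L))
  nlv <- dcv@modalLV

  say("stage fixed-#LV protocols (#LV = ", nlv, ")")
  boot <- .stageTry("bootstrap",
    bootstrapValidation(view, iterations = config$protocolIterations,
                        nLV = nlv, seed = config$seed + 4L))
  subs <- .stageTry("subsampling",
    subsamplingValidation(view, iterations = config$protocolIterations,
                          trainFraction = config$trainFraction, nLV = nlv,
                          seed = config$seed + 5L))
  ks <- .stageTry("kennard_stone",
    kennardStoneValidation(view, nLV = nlv, stratified = TRUE,
                           trainFraction = config$trainFraction))
  ksp <- .stageTry("kennard_stone",
    kennardStoneValidation(view, nLV = nlv, stratified = FALSE,
                           trainFraction = config$trainFraction))

  say("stage LDA branch")
  ldaPrep <- .stageTry("lda", prepareLDAVariables(
    view, sel, alpha = config$alphaLilliefors,
    pThreshold = config$pThreshold))
  ldaRep <- .stageTry("lda", crossvalidateLDA(
    ldaPrep$table, repetitions = config$protocolIterations,
    trainFraction = config$trainFraction, seed = config$seed + 6L))

  say("stage permutation test")
  refNMC <- round(mean(dcv@diagnostics$nmc))
  perm <- .stageTry("permutation",
    permutationTest(view, nPermutations = config$nPermutations, nLV = nlv,
                    referenceNMC = refNMC, seed = config$seed + 7L))

  say("stage reports")
  .stageTry("reports", {
    out <- config$outputDir
    selOut <- ldaPrep$selection
    write.csv(selOut, file.path(out, "selection.csv"), row.names = FALSE)
    reports <- list(double_cv = dcv, bootstrap = boot, subsampling = subs,
                    kennard_stone_stratified = ks, kennard_stone = ksp,
                    lda_cv = ldaRep)
    diag_tab <- do.call(cbind, lapply(reports, function(r)
      unlist(r@summary["mean", ])))
    write.csv(round(diag_tab, 4), file.path(out, "diagnostics.csv"))
    for (nm in names(reports))
      write.csv(reports[[nm]]@diagnostics,
                file.path(out, paste0("repetitions_", nm, ".csv")),
                row.names = FALSE)
    write.csv(data.frame(nmc = perm@nmcPerm),
              file.path(out, "permutation_h0.csv"), row.names = FALSE)
    write.csv(data.frame(observed_nmc = perm@observedNMC,
                         count = perm@count, p_value = perm@pValue,
                         n_permutations = perm@nPermutations,
                         h0_mean = mean(perm@nmcPerm)),
              file.path(out, "permutation_summary.csv"), row.names = FALSE)
    write.csv(data.frame(run = names(outl$flags), od = outl$od,
                         t2 = outl$t2, flagged = outl$flags),
              file.path(out, "outliers.csv"), row.names = FALSE)
    cfg_out <- config
    cfg_out$generator <- list(
      nCheesesPerClass = config$generator@nCheesesPerClass,
      replicatesPerCheese = config$generator@replicatesPerCheese,
      cheeseEffectSdFrac = config$generator@cheeseEffectSdFrac,
      nonmarkerCV = config$generator@nonmarkerCV,
      distribution = config$generator@distribution,
      seed = config$generator@seed)
    jsonlite::write_json(cfg_out, file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(list(table = tab, view = view, pca = pca, outliers = outl,
                 selection = ldaPrep$selection, doubleCV = dcv,
                 bootstrap = boot, subsampling = subs, kennardStone = ks,
                 kennardStonePlain = ksp, ldaPrep = ldaPrep, lda = ldaRep,
                 permutation = perm, outputDir = config$outputDir))
}
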