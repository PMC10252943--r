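#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats pf pchisq qchisq sd var rnorm runif prcomp setNames
#'   dist cov
#' @importFrom utils read.csv write.csv
NULL

.SUBCLASSES <- c("TG", "DG", "BisMePA", "PEt", "ChE", "Cer", "HexCer",
                 "MGDG", "LPC", "PC", "SM", "LPE", "PA", "PE", "PI", "PS")
.ION_MODES <- c("positive", "negative")
.CLASSES <- c("NI", "IRR")
.MODEL_TAGS <- c("PLS-DA", "LDA")

#' LipidFeatureTable: a two-class lipid feature table
#'
#' Container for a runs x lipids matrix of chromatographic peak areas
#' (arbitrary units x 1e5) with a class label (`NI` non-irradiated /
#' `IRR` irradiated), cheese id and replicate per run, and per-lipid
#' annotation (subclass, ion mode, oxidation tag, marker-model tags and,
#' for catalog markers, the per-class generating mean/SD).
#'
#' Internally the object extends
#' [SummarizedExperiment::SummarizedExperiment] with lipids as rows and
#' runs as columns (the Bioconductor convention); the user-facing
#' accessors [areaMatrix()] etc. present the runs x lipids orientation
#' used by the modelling functions.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [LipidFeatureTable()] the constructor, [areaMatrix()],
#'   [classLabels()], [lipidMeta()], [ionModeView()]
#' @export
setClass("LipidFeatureTable", contains = "SummarizedExperiment")

setValidity("LipidFeatureTable", function(object) {
  a <- SummarizedExperiment::assay(object, "areas")
  msg <- character()
  if (anyNA(a))
    msg <- c(msg, "areas contain missing values")
  # log-transformed sub-tables (LDA preparation) may legitimately hold
  # negative values; raw peak areas may not
  if (!isTRUE(S4Vectors::metadata(object)$transformed) &&
      any(a < 0, na.rm = TRUE))
    msg <- c(msg, "areas contain negative values")
  cd <- SummarizedExperiment::colData(object)
  if (!"class" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'class' column")
  else if (!all(cd$class %in% .CLASSES))
    msg <- c(msg, "class labels must be 'NI' or 'IRR'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate lipid ids")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("subclass", "ion_mode") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'subclass' and 'ion_mode'")
  if (length(msg)) msg else TRUE
})

#' Synthetic-data generator configuration
#'
#' Defines the design and noise structure of a generated feature table:
#' the balanced two-class design (cheeses per class x replicates per
#' cheese), how much of each species' variance is attributed to the
#' between-cheese component, the coefficient of variation of the
#' class-free (non-marker) species, the sampling distribution, and the
#' RNG seed.
#'
#' @slot nCheesesPerClass integer, cheeses per class (default 4).
#' @slot replicatesPerCheese integer, runs per cheese (default 3).
#' @slot cheeseEffectSdFrac numeric in `[0, 1)`, fraction of each
#'   species' variance assigned to the shared between-cheese effect
#'   (default 0.3; 0 gives i.i.d. runs).
#' @slot nonmarkerCV numeric, coefficient of variation of non-marker
#'   species (default 0.25).
#' @slot distribution `"truncated_normal"` (default) or `"lognormal"`.
#' @slot seed integer RNG seed.
#' @seealso [generatorConfig()], [generateDataset()]
#' @export
setClass("GeneratorConfig",
  representation(nCheesesPerClass = "integer",
                 replicatesPerCheese = "integer",
                 cheeseEffectSdFrac = "numeric",
                 nonmarkerCV = "numeric",
                 distribution = "character",
                 seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nCheesesPerClass < 1L || object@replicatesPerCheese < 1L)
    msg <- c(msg, "counts must be >= 1")
  if (object@cheeseEffectSdFrac < 0 || object@cheeseEffectSdFrac >= 1)
    msg <- c(msg, "cheeseEffectSdFrac must be in [0, 1)")
  if (object@nonmarkerCV <= 0)
    msg <- c(msg, "nonmarkerCV must be > 0")
  if (!object@distribution %in% c("truncated_normal", "lognormal"))
    msg <- c(msg, "distribution must be 'truncated_normal' or 'lognormal'")
  if (length(msg)) msg else TRUE
})

#' One model-evaluation's diagnostic statistics
#'
#' Scalar quality measures of a two-class discriminant model evaluated
#' on (cross-)validation predictions: Q2 (cross-validated explained
#' deviance), DQ2 (its discriminant variant that does not penalise
#' predictions beyond the class target), sensitivity, specificity,
#' accuracy, AUROC, RMSECV, its `[0, 1]` rescaling tRMSECV, the
#' efficiency index (sum of the previous seven), and the number of
#' misclassified runs (NMC). `tRMSECV` and `iEff` are `NA` outside a
#' latent-variable scan, where no RMSECV range exists.
#'
#' @seealso [diagnosticSet()], [iEff()]
#' @export
setClass("DiagnosticSet",
  representation(q2 = "numeric", dq2 = "numeric", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric",
                 auroc = "numeric", rmsecv = "numeric", trmsecv = "numeric",
                 iEff = "numeric", nmc = "numeric", n = "integer"))

setValidity("DiagnosticSet", function(object) {
  msg <- character()
  inunit <- function(x) is.na(x) || (x >= 0 && x <= 1)
  for (s in c("sensitivity", "specificity", "accuracy", "auroc", "trmsecv"))
    if (!inunit(slot(object, s)))
      msg <- c(msg, paste(s, "must lie in [0, 1]"))
  if (!is.na(object@dq2) && !is.na(object@q2) &&
      object@dq2 < object@q2 - 1e-10)
    msg <- c(msg, "dq2 must be >= q2")
  if (length(msg)) msg else TRUE
})

#' Fitted two-class PLS1 discriminant model
#'
#' NIPALS PLS1 regression of the class coding (`IRR` = +1, `NI` = -1)
#' on the preprocessed area matrix. Stores the preprocessing vectors,
#' per-component weights/loadings, training scores and the explained
#' response sum of squares per component (used by VIP).
#'
#' @seealso [fitPLS()], [predictPLS()], [vipScores()]
#' @export
setClass("PLSModel",
  representation(nLV = "integer", weights = "matrix", loadings = "matrix",
                 yLoadings = "numeric", scores = "matrix", ssy = "numeric",
                 xCenter = "numeric", xScale = "numeric", yMean = "numeric",
                 lipids = "character", autoscale = "logical",
                 dropped = "character"))

#' Fitted two-class linear discriminant model
#'
#' Pooled-covariance LDA with equal priors: class mean vectors, the
#' pooled within-class covariance (ridge-stabilised when near-singular)
#' and the resulting discriminant direction and threshold.
#'
#' @seealso [fitLDA()], [predictLDA()]
#' @export
setClass("LDAModel",
  representation(meanNI = "numeric", meanIRR = "numeric",
                 pooledCov = "matrix", direction = "numeric",
                 threshold = "numeric", variables = "character",
                 ridge = "numeric", priors = "numeric"))

#' Principal component analysis with outlier distances
#'
#' SVD-based PCA on the autoscaled area matrix with, for a chosen
#' component count, the per-run normalised orthogonal distance and
#' normalised Hotelling T2 distance used for outlier screening.
#'
#' @seealso [pcaFit()], [outlierScreen()]
#' @export
setClass("PCAResult",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", nComponents = "integer",
                 od = "numeric", t2 = "numeric",
                 center = "numeric", scale = "numeric", runs = "character"))

#' Validation protocol report
#'
#' Per-repetition diagnostic statistics for one validation protocol
#' (double cross-validation, bootstrap, stratified subsampling,
#' Kennard-Stone or repeated LDA cross-validation), their
#' means/dispersions, and the latent-variable counts involved.
#'
#' @seealso [doubleCrossValidation()], [bootstrapValidation()],
#'   [subsamplingValidation()], [kennardStoneValidation()],
#'   [crossvalidateLDA()]
#' @export
setClass("ValidationReport",
  representation(protocol = "character", diagnostics = "data.frame",
                 summary = "data.frame", nLV = "numeric",
                 modalLV = "numeric", seed = "numeric", extra = "list"))

setValidity("ValidationReport", function(object) {
  d <- object@diagnostics
  s <- object@summary
  msg <- character()
  for (col in intersect(colnames(s), colnames(d))) {
    m <- if ("mean" %in% rownames(s)) s["mean", col] else NA_real_
    if (length(m) == 1L && is.finite(m) &&
        (m < min(d[[col]], na.rm = TRUE) - 1e-9 ||
         m > max(d[[col]], na.rm = TRUE) + 1e-9))
      msg <- c(msg, paste("summary mean of", col, "outside per-repetition range"))
  }
  if (length(msg)) msg else TRUE
})

#' Permutation-test result
#'
#' Null distribution of the number of misclassified samples (NMC) under
#' random relabelling, the observed reference NMC, and the p-value
#' `(1 + #(NMC_perm <= NMC)) / N`.
#'
#' @seealso [permutationTest()], [permutationPValue()]
#' @export
setClass("PermutationResult",
  representation(observedNMC = "numeric", nmcPerm = "integer",
                 count = "integer", pValue = "numeric",
                 nPermutations = "integer", nRuns = "integer",
                 seed = "numeric"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@pValue < 1 / object@nPermutations - 1e-12)
    msg <- c(msg, "p-value below the 1/N floor")
  if (any(object@nmcPerm < 0L | object@nmcPerm > object@nRuns))
    msg <- c(msg, "permuted NMC outside [0, n]")
  if (length(msg)) msg else TRUE
})
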