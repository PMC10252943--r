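#' Construct a LipidFeatureTable
#'
#' @param areas numeric matrix, runs x lipids, non-negative peak areas
#'   (AU x 1e5). Column names are lipid ids, row names run ids (generated
#'   if absent).
#' @param classes character/factor of length `nrow(areas)` with values
#'   `"NI"` or `"IRR"`.
#' @param cheese,replicate optional per-run integer metadata.
#' @param lipidData optional `data.frame`/`DataFrame` of per-lipid
#'   annotation with at least `subclass` and `ion_mode`; one row per
#'   column of `areas`, in order. When omitted both are set to `NA`.
#' @param transformed mark the values as transformed (e.g. log) rather
#'   than raw areas; lifts the non-negativity requirement.
#' @return A [LipidFeatureTable-class] object.
#' @examples
#' a <- matrix(runif(40, 1, 10), 4, 10,
#'             dimnames = list(NULL, paste0("L", 1:10)))
#' tab <- LipidFeatureTable(a, classes = c("NI", "NI", "IRR", "IRR"))
#' nRuns(tab)
#' @export
LipidFeatureTable <- function(areas, classes, cheese = NA_integer_,
                              replicate = NA_integer_, lipidData = NULL,
                              transformed = FALSE) {
  areas <- as.matrix(areas)
  if (is.null(colnames(areas)))
    colnames(areas) <- sprintf("lipid_%03d", seq_len(ncol(areas)))
  if (is.null(rownames(areas)))
    rownames(areas) <- sprintf("run_%02d", seq_len(nrow(areas)))
  classes <- as.character(classes)
  if (length(classes) != nrow(areas))
    stop("length of 'classes' must equal the number of runs")
  if (is.null(lipidData))
    lipidData <- data.frame(subclass = rep(NA_character_, ncol(areas)),
                            ion_mode = rep(NA_character_, ncol(areas)),
                            row.names = colnames(areas))
  rd <- S4Vectors::DataFrame(lipidData, row.names = colnames(areas))
  if (!"oxidation" %in% colnames(rd)) rd$oxidation <- NA_character_
  if (!"models" %in% colnames(rd)) rd$models <- ""
  cd <- S4Vectors::DataFrame(class = classes,
                             cheese = rep(as.integer(cheese), length.out = nrow(areas)),
                             replicate = rep(as.integer(replicate), length.out = nrow(areas)),
                             row.names = rownames(areas))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(areas = t(areas)), rowData = rd, colData = cd,
    metadata = list(transformed = isTRUE(transformed)))
  methods::new("LipidFeatureTable", se)
}

#' Accessors for LipidFeatureTable
#'
#' `areaMatrix()` returns the runs x lipids area matrix; `classLabels()`
#' the per-run class factor (levels `NI`, `IRR`); `classCoding()` the
#' numeric coding used by the discriminant models (`IRR` = +1,
#' `NI` = -1); `runMeta()` and `lipidMeta()` the run and lipid
#' annotation; `nRuns()`/`nLipids()` the dimensions.
#'
#' @param x a [LipidFeatureTable-class].
#' @return See each description.
#' @name featureTableAccessors
#' @aliases areaMatrix classLabels classCoding runMeta lipidMeta nRuns nLipids
NULL

#' @rdname featureTableAccessors
#' @export
areaMatrix <- function(x) t(SummarizedExperiment::assay(x, "areas"))

#' @rdname featureTableAccessors
#' @export
classLabels <- function(x)
  factor(SummarizedExperiment::colData(x)$class, levels = .CLASSES)

#' @rdname featureTableAccessors
#' @export
classCoding <- function(x) ifelse(classLabels(x) == "IRR", 1, -1)

#' @rdname featureTableAccessors
#' @export
runMeta <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @rdname featureTableAccessors
#' @export
lipidMeta <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname featureTableAccessors
#' @export
nRuns <- function(x) ncol(x)

#' @rdname featureTableAccessors
#' @export
nLipids <- function(x) nrow(x)

#' Subset a feature table to one ion mode or a lipid set
#'
#' `ionModeView()` restricts the table to the lipids acquired in the
#' given ion mode. `lipidView()` restricts to an explicit set of lipid
#' ids (order preserved as given).
#'
#' @param x a [LipidFeatureTable-class].
#' @param mode `"positive"` or `"negative"`.
#' @param lipids character vector of lipid ids present in `x`.
#' @return A [LipidFeatureTable-class] with the selected lipid columns.
#' @export
ionModeView <- function(x, mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  keep <- lipidMeta(x)$ion_mode == mode
  if (!any(keep, na.rm = TRUE))
    stop("no lipids in ion mode '", mode, "'")
  x[which(keep), ]
}

#' @rdname ionModeView
#' @export
lipidView <- function(x, lipids) {
  miss <- setdiff(lipids, rownames(x))
  if (length(miss))
    stop("lipids not in table: ", paste(miss, collapse = ", "))
  x[lipids, ]
}

#' @describeIn LipidFeatureTable-class compact display.
#' @param object a `LipidFeatureTable`.
#' @export
setMethod("show", "LipidFeatureTable", function(object) {
  cl <- table(classLabels(object))
  cat("LipidFeatureTable:", ncol(object), "runs x", nrow(object), "lipids\n")
  cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  im <- table(SummarizedExperiment::rowData(object)$ion_mode, useNA = "ifany")
  cat("  ion modes:", paste(names(im), im, sep = "=", collapse = ", "), "\n")
  sc <- unique(SummarizedExperiment::rowData(object)$subclass)
  cat("  subclasses:", length(sc[!is.na(sc)]), "\n")
})

# both classes with at least `min_per_class` runs, or stop with the caller's
# operation name
.assertTwoClass <- function(x, min_per_class = 1L, what = "this operation") {
  cl <- table(classLabels(x))
  if (length(cl) < 2L || any(cl < min_per_class))
    stop(what, " requires both classes with at least ", min_per_class,
         " run(s); got ", paste(names(cl), cl, sep = "=", collapse = ", "))
  invisible(TRUE)
}
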