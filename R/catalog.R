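#' Load the packaged marker catalog
#'
#' Reads the catalog of the 42 lipid species found to discriminate
#' irradiated (`IRR`) from non-irradiated (`NI`) Camembert, with, per
#' species: subclass, ion mode, oxidation tag, the discriminant model(s)
#' it was selected by (`PLS-DA`, `LDA` or both), and the per-class mean
#' and SD of its peak area (AU x 1e5, means of sums over n = 12 runs).
#' These means/SDs parameterise the synthetic-data generator.
#'
#' @param path optional path to a catalog CSV with columns
#'   `lipid_id, subclass, ion_mode, oxidation, models, mean_NI, sd_NI,
#'   mean_IRR, sd_IRR`; defaults to the packaged fixture.
#' @return A `data.frame`, one row per marker species, with a
#'   `marker_models` list column of model tags.
#' @examples
#' cat42 <- loadMarkerCatalog()
#' nrow(cat42)                      # 42
#' countMarkers(cat42, "PLS-DA")    # 40
#' @export
loadMarkerCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "marker_catalog.csv", package = "lipidisc",
                        mustWork = FALSE)
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("marker catalog fixture not found: ",
         if (is.null(path) || !nzchar(path)) "marker_catalog.csv" else path)
  cat_df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("lipid_id", "subclass", "ion_mode", "oxidation", "models",
            "mean_NI", "sd_NI", "mean_IRR", "sd_IRR")
  if (!all(need %in% colnames(cat_df)))
    stop("corrupt marker catalog '", path, "': missing column(s) ",
         paste(setdiff(need, colnames(cat_df)), collapse = ", "))
  cat_df$marker_models <- strsplit(cat_df$models, "/", fixed = TRUE)
  bad <- !vapply(cat_df$marker_models,
                 function(m) length(m) >= 1L && all(m %in% .MODEL_TAGS),
                 logical(1))
  if (any(bad))
    stop("corrupt marker catalog '", path, "': bad model tags in rows ",
         paste(which(bad), collapse = ", "))
  with(cat_df, {
    if (any(mean_NI <= 0 | mean_IRR <= 0 | sd_NI <= 0 | sd_IRR <= 0))
      stop("corrupt marker catalog '", path, "': non-positive mean/SD")
    if (!all(subclass %in% .SUBCLASSES) || !all(ion_mode %in% .ION_MODES))
      stop("corrupt marker catalog '", path, "': unknown subclass/ion mode")
  })
  if (anyDuplicated(cat_df$lipid_id))
    stop("corrupt marker catalog '", path, "': duplicate lipid ids")
  cat_df
}

#' Count catalog markers by discriminant model
#'
#' @param catalog a catalog from [loadMarkerCatalog()].
#' @param model `"PLS-DA"`, `"LDA"`, or `"union"` (any tag).
#' @return integer count of species whose `marker_models` contains the
#'   tag.
#' @examples
#' cat42 <- loadMarkerCatalog()
#' countMarkers(cat42, "LDA")     # 24
#' countMarkers(cat42, "union")   # 42
#' @export
countMarkers <- function(catalog, model = c("union", .MODEL_TAGS)) {
  model <- match.arg(model)
  if (model == "union")
    return(sum(lengths(catalog$marker_models) > 0L))
  sum(vapply(catalog$marker_models, function(m) model %in% m, logical(1)))
}

#' Load the packaged lipid-subclass census
#'
#' The census of the 479 lipid species identified in Camembert: counts
#' per subclass x ion mode x oxidation tag (oxidized species are filed
#' under their parent subclass, so the census spans exactly 16
#' subclasses). Used by the generator to lay out the full species list.
#'
#' @param path optional path to a census CSV (`subclass, ion_mode,
#'   oxidation, n`); defaults to the packaged fixture.
#' @return A `data.frame` with one row per subclass/mode/oxidation cell.
#' @examples
#' census <- loadSubclassCensus()
#' sum(census$n)                       # 479
#' length(unique(census$subclass))     # 16
#' @export
loadSubclassCensus <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "subclass_census.csv", package = "lipidisc",
                        mustWork = FALSE)
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("subclass census fixture not found")
  cen <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subclass", "ion_mode", "oxidation", "n") %in% colnames(cen)) ||
      any(cen$n < 0) || !all(cen$subclass %in% .SUBCLASSES))
    stop("corrupt subclass census '", path, "'")
  cen
}
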