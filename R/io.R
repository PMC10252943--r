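#' Read and write feature tables as CSV
#'
#' The feature-table CSV has one row per run with columns
#' `run_id, class, cheese, replicate, <lipid_id_1>, ...`. Lipid
#' annotation travels in an optional sidecar CSV (`lipid_id, subclass,
#' ion_mode, oxidation, models`); without it, annotation read back is
#' `NA` (the subclass is inferred from the id prefix where possible).
#'
#' @param path CSV file path.
#' @param lipidMetaPath optional sidecar CSV path for lipid annotation.
#' @param x a [LipidFeatureTable-class] to write.
#' @return `readFeatureTable()` a [LipidFeatureTable-class];
#'   `writeFeatureTable()` invisibly the main `path`.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' a <- matrix(runif(20, 1, 5), 2, 10,
#'             dimnames = list(NULL, paste0("L", 1:10)))
#' writeFeatureTable(LipidFeatureTable(a, c("NI", "IRR")), tmp)
#' readFeatureTable(tmp)
#' @export
readFeatureTable <- function(path, lipidMetaPath = NULL) {
  if (!file.exists(path)) stop("feature table file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("run_id", "class", "cheese", "replicate")
  miss <- setdiff(c("run_id", "class"), colnames(df))
  if (length(miss))
    stop("feature table CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  lipid_cols <- colnames(df)[!colnames(df) %in% meta_cols]
  if (!length(lipid_cols)) stop("feature table CSV has no lipid columns")
  dup <- unique(lipid_cols[duplicated(lipid_cols)])
  if (length(dup))
    stop("duplicate lipid ids in CSV: ", paste(dup, collapse = ", "))
  areas <- as.matrix(df[, !colnames(df) %in% meta_cols, drop = FALSE])
  rownames(areas) <- df$run_id
  if (!is.numeric(areas))
    stop("non-numeric areas in the lipid columns")
  if (anyNA(areas)) {
    bad <- lipid_cols[colSums(is.na(areas)) > 0]
    stop("missing areas in column(s): ", paste(unique(bad), collapse = ", "))
  }
  neg <- lipid_cols[colSums(areas < 0) > 0]
  if (length(neg))
    stop("negative areas in column(s): ", paste(neg, collapse = ", "))
  if (anyNA(df$class) || !all(df$class %in% .CLASSES))
    stop("invalid or missing class labels (must be 'NI'/'IRR') in rows: ",
         paste(which(is.na(df$class) | !df$class %in% .CLASSES),
               collapse = ", "))
  lipidData <- NULL
  if (!is.null(lipidMetaPath)) {
    lm <- read.csv(lipidMetaPath, check.names = FALSE,
                   stringsAsFactors = FALSE)
    rownames(lm) <- lm$lipid_id
    lipidData <- lm[lipid_cols, setdiff(colnames(lm), "lipid_id"),
                    drop = FALSE]
  } else {
    # best-effort subclass from the id prefix, e.g. "PE (18:2_18:2)" -> PE
    pre <- sub("^([A-Za-z0-9]+).*$", "\\1", lipid_cols)
    pre[pre %in% c("Hex1Cer", "Hex2Cer", "OxHex1Cer")] <- "HexCer"
    lipidData <- data.frame(
      subclass = ifelse(pre %in% .SUBCLASSES, pre, NA_character_),
      ion_mode = NA_character_, row.names = lipid_cols)
  }
  LipidFeatureTable(areas, classes = df$class,
                    cheese = if ("cheese" %in% colnames(df)) df$cheese else NA,
                    replicate = if ("replicate" %in% colnames(df))
                      df$replicate else NA,
                    lipidData = lipidData)
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(x, path, lipidMetaPath = NULL) {
  stopifnot(methods::is(x, "LipidFeatureTable"))
  rm <- runMeta(x)
  out <- data.frame(run_id = rownames(rm), class = rm$class,
                    cheese = rm$cheese, replicate = rm$replicate,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(areaMatrix(x), check.names = FALSE))
  write.csv(out, path, row.names = FALSE)
  if (!is.null(lipidMetaPath)) {
    lm <- lipidMeta(x)
    lm$models <- vapply(lm$models, function(m)
      paste(unlist(m), collapse = "/"), character(1))
    write.csv(cbind(lipid_id = rownames(lm), lm), lipidMetaPath,
              row.names = FALSE)
  }
  invisible(path)
}
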