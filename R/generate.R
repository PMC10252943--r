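#' Create a generator configuration
#'
#' @param nCheesesPerClass cheeses per class (default 4, giving the
#'   study's 4 x 3 = 12 runs per class with the default replicates).
#' @param replicatesPerCheese analytical replicates per cheese
#'   (default 3).
#' @param cheeseEffectSdFrac fraction of each species' variance placed
#'   in a shared between-cheese effect (default 0.3; 0 = i.i.d. runs).
#' @param nonmarkerCV coefficient of variation of the class-free
#'   species (default 0.25).
#' @param distribution `"truncated_normal"` (default, floor 1e-3
#'   AU x 1e5) or `"lognormal"` (moment-matched).
#' @param seed integer RNG seed.
#' @return A [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(seed = 1)
#' @export
generatorConfig <- function(nCheesesPerClass = 4L, replicatesPerCheese = 3L,
                            cheeseEffectSdFrac = 0.3, nonmarkerCV = 0.25,
                            distribution = c("truncated_normal", "lognormal"),
                            seed = 1L) {
  methods::new("GeneratorConfig",
               nCheesesPerClass = as.integer(nCheesesPerClass),
               replicatesPerCheese = as.integer(replicatesPerCheese),
               cheeseEffectSdFrac = cheeseEffectSdFrac,
               nonmarkerCV = nonmarkerCV,
               distribution = match.arg(distribution),
               seed = as.integer(seed))
}

# area floor on the AU x 1e5 scale for truncated-normal draws
.AREA_FLOOR <- 1e-3

# draw n values with given mean/sd, a between-cheese variance share f,
# and the configured distribution; cheese is the per-run cheese index
.drawSpecies <- function(mean, sd, cheese, f, distribution) {
  ncheese <- max(cheese)
  n <- length(cheese)
  if (distribution == "truncated_normal") {
    b <- rnorm(ncheese, 0, sd * sqrt(f))[cheese]
    v <- mean + b + rnorm(n, 0, sd * sqrt(1 - f))
    for (i in seq_len(100)) {
      low <- v < .AREA_FLOOR
      if (!any(low)) break
      v[low] <- mean + b[low] + rnorm(sum(low), 0, sd * sqrt(1 - f))
    }
    pmax(v, .AREA_FLOOR)
  } else {
    s2 <- log(1 + (sd / mean)^2)
    mu <- log(mean) - s2 / 2
    b <- rnorm(ncheese, 0, sqrt(s2 * f))[cheese]
    exp(mu + b + rnorm(n, 0, sqrt(s2 * (1 - f))))
  }
}

.speciesLayout <- function(catalog, census) {
  key <- function(d) paste(d$subclass, d$ion_mode, d$oxidation, sep = "|")
  ck <- key(catalog)
  rows <- list()
  for (i in seq_len(nrow(census))) {
    cell <- census[i, ]
    hit <- which(ck == key(cell))
    n_fill <- cell$n - length(hit)
    if (n_fill < 0)
      stop("census cell ", key(cell), " smaller than its marker count")
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        lipid_id = catalog$lipid_id[hit], subclass = cell$subclass,
        ion_mode = cell$ion_mode, oxidation = cell$oxidation,
        models = catalog$models[hit], mean_NI = catalog$mean_NI[hit],
        sd_NI = catalog$sd_NI[hit], mean_IRR = catalog$mean_IRR[hit],
        sd_IRR = catalog$sd_IRR[hit], stringsAsFactors = FALSE)
    if (n_fill > 0) {
      suffix <- c(none = "", long_chain_O = "+O", CHO = "-CHO",
                  COOH = "-COOH", COOCH3 = "-COOCH3")[cell$oxidation]
      rows[[length(rows) + 1L]] <- data.frame(
        lipid_id = sprintf("%s (syn%s-%03d)", cell$subclass, suffix,
                           seq_len(n_fill)),
        subclass = cell$subclass, ion_mode = cell$ion_mode,
        oxidation = cell$oxidation, models = "",
        mean_NI = NA_real_, sd_NI = NA_real_, mean_IRR = NA_real_,
        sd_IRR = NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic two-class lipid feature table
#'
#' Emulates the Camembert study table: a balanced design of
#' `nCheesesPerClass x replicatesPerCheese` runs per class (`NI`,
#' `IRR`) over the full 479-species catalog+census layout. The 42
#' catalog markers are drawn per class from their printed mean/SD; the
#' remaining species have no class effect, with a per-species mean
#' sampled log-uniformly between 10 and 1000 AU x 1e5 and
#' SD = `nonmarkerCV` x mean. Each species' variance is split into a
#' shared between-cheese effect (`cheeseEffectSdFrac` of the variance)
#' and replicate noise, so the total SD matches the catalog value. All
#' areas are positive.
#'
#' `generateNullDataset()` removes every class effect: markers too are
#' drawn, in both classes, from the pooled mean `(mean_NI + mean_IRR)/2`
#' and pooled SD `sqrt((sd_NI^2 + sd_IRR^2)/2)` — a null surface for
#' permutation and type-I-error checks.
#'
#' @param config a [generatorConfig()].
#' @param catalog a catalog from [loadMarkerCatalog()].
#' @param census a census from [loadSubclassCensus()].
#' @return A [LipidFeatureTable-class] (default design: 24 runs x 479
#'   lipids across 16 subclasses).
#' @examples
#' tab <- generateDataset(generatorConfig(seed = 7), loadMarkerCatalog())
#' tab
#' @export
generateDataset <- function(config = generatorConfig(),
                            catalog = loadMarkerCatalog(),
                            census = loadSubclassCensus()) {
  .generate(config, catalog, census, null = FALSE)
}

#' @rdname generateDataset
#' @export
generateNullDataset <- function(config = generatorConfig(),
                                catalog = loadMarkerCatalog(),
                                census = loadSubclassCensus()) {
  .generate(config, catalog, census, null = TRUE)
}

.generate <- function(config, catalog, census, null) {
  methods::validObject(config)
  layout <- .speciesLayout(catalog, census)
  set.seed(config@seed)
  n_per <- config@nCheesesPerClass * config@replicatesPerCheese
  cheese <- rep(seq_len(config@nCheesesPerClass),
                each = config@replicatesPerCheese)
  repl <- rep(seq_len(config@replicatesPerCheese), config@nCheesesPerClass)
  classes <- rep(.CLASSES, each = n_per)
  run_ids <- paste0(classes, "_c", c(cheese, cheese), "_r", c(repl, repl))

  p <- nrow(layout)
  is_marker <- nzchar(layout$models)
  # class-free means for non-markers, log-uniform over the catalog's
  # non-oxidized magnitude range
  m_free <- exp(runif(p, log(10), log(1000)))
  mean_ni <- ifelse(is_marker, layout$mean_NI, m_free)
  mean_irr <- ifelse(is_marker, layout$mean_IRR, m_free)
  sd_ni <- ifelse(is_marker, layout$sd_NI, config@nonmarkerCV * m_free)
  sd_irr <- ifelse(is_marker, layout$sd_IRR, config@nonmarkerCV * m_free)
  if (null) {
    pooled_m <- (mean_ni + mean_irr) / 2
    pooled_s <- sqrt((sd_ni^2 + sd_irr^2) / 2)
    mean_ni <- mean_irr <- pooled_m
    sd_ni <- sd_irr <- pooled_s
  }
  areas <- matrix(NA_real_, nrow = 2L * n_per, ncol = p,
                  dimnames = list(run_ids, layout$lipid_id))
  f <- config@cheeseEffectSdFrac
  for (j in seq_len(p)) {
    areas[seq_len(n_per), j] <-
      .drawSpecies(mean_ni[j], sd_ni[j], cheese, f, config@distribution)
    areas[n_per + seq_len(n_per), j] <-
      .drawSpecies(mean_irr[j], sd_irr[j], cheese, f, config@distribution)
  }
  lipidData <- layout[, c("subclass", "ion_mode", "oxidation", "models",
                          "mean_NI", "sd_NI", "mean_IRR", "sd_IRR")]
  rownames(lipidData) <- layout$lipid_id
  LipidFeatureTable(areas, classes = classes, cheese = c(cheese, cheese),
                    replicate = c(repl, repl), lipidData = lipidData)
}
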