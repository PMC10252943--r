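Package: lipidisc
Title: Chemometric Discrimination of Two-Class Untargeted Lipidomics Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker selection and supervised classification for two-class
    untargeted lipidomics feature tables (peak areas of lipid species across
    runs), motivated by food-irradiation authentication of soft cheese.
    Provides volcano-plot and VIP-score marker screening, PLS-DA and LDA
    classifiers, and a full validation stack: discriminant Q2/DQ2 diagnostics,
    an efficiency index combining seven cross-validated statistics for
    latent-variable selection, repeated double cross-validation, bootstrap,
    stratified random subsampling, Kennard-Stone sampling, and a
    permutation test on the number of misclassifications. A synthetic-data
    generator emulates an irradiated/non-irradiated Camembert lipid table
    (479 species in 16 subclasses) from a packaged marker catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
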