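Package: popgrid
Title: Population Spatialization with Feature Selection and
    Cluster-Balanced Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Disaggregates census population counts from administrative
    units onto a regular grid (dasymetric mapping) using multi-source
    gridded covariates. Provides covariate engineering (terrain summaries,
    nighttime-light correction, point-of-interest kernel density surfaces,
    zonal statistics), three comparative feature-selection routes (maximal
    information coefficient, recursive feature elimination with
    cross-validation, permutation importance), K-means++ clustering with
    elbow-based choice of k, a cluster-balanced bootstrap random forest for
    imbalanced density regression, an out-of-bag-error-weighted forest
    variant, and a predict-aggregate-evaluate pipeline with relative-error
    reporting. Includes a synthetic-landscape generator with known
    generative coefficients so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
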