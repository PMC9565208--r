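Package: somprofiles
Title: Self-Organizing Map Profiling of Physical Performance and Body
    Composition in Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps six-variable physical performance and body composition
    profiles of community-dwelling older adults onto a hexagonal
    self-organizing map, hierarchically clusters the trained codebook into
    severity-ordered profile groups, and characterizes the groups with a
    normality-gated pairwise test cascade (ANOVA/Tukey, Welch/Games-Howell,
    Kruskal-Wallis/Dunn), univariate multinomial logistic relative risk
    ratios, and Poisson rate ratios for comorbidity counts. Includes a
    synthetic cohort generator parameterized by published per-cluster
    centroids and prevalences so the full pipeline is testable offline,
    plus hexagon-tiled component-plane and cluster-map renderings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    car,
    cluster,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    mclust,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
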