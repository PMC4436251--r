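Package: betanest
Title: Partitioning Beta Diversity into Turnover and Nestedness Components
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Incidence-based beta-diversity analysis for fragmented
    landscapes and island systems. Partitions pairwise and multiple-site
    Sorensen dissimilarity into spatial-turnover and nestedness-resultant
    components (with Jaccard and Carvalho alternatives), quantifies
    nestedness with the NODF metric under a proportional-proportional
    (PP) randomization null, and relates dissimilarity matrices to
    differences in island attributes via Mantel, partial Mantel and
    multiple regression on distance matrices (MRM). Includes species-area
    regression with backward AIC selection, generators of synthetic
    community matrices with controlled nested/turnover structure, the
    attribute table of a 37-island land-bridge study system, and a
    pipeline that reproduces the full analysis from community and
    attribute tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
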