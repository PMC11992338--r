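Package: fatesimplex
Title: Simplex Maps of Single-Cell Fate Commitment and Differentiation
    Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places each cell of a single-cell RNA or ATAC dataset inside a
    2-4 vertex simplex whose vertices are user-chosen terminal cell types.
    Marker genes for each terminal fate are ranked by Wilcoxon rank-sum
    test, Euclidean distances from cells to terminal-cluster centroids are
    converted to similarities with an exponential kernel, range-scaled per
    vertex, and L1-normalized into barycentric coordinates. An optional
    cell-cell transition graph (e.g. from RNA velocity) is aggregated into
    grid-binned fate-potential arrows overlaid on ternary, quaternary, or
    segment plots. Includes a synthetic-data generator with known ground
    truth for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
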