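Package: benthochange
Title: Change Detection for Benthic Foundation Species from Repeat Photomosaic Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting abundance and condition change in cold-water
    coral and sponge populations between repeat georeferenced photomosaic
    surveys. Matches annotated individuals between baseline and revisit
    surveys, computes a frequency-weighted severity-scaled condition score,
    per-taxon percent abundance change, oxygen-minimum-zone classification
    from dissolved oxygen series, and an exact nonparametric test battery
    (signed-rank, rank-sum, Kruskal-Wallis with Dunn's post hoc). Includes a
    synthetic two-timepoint survey generator with ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
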