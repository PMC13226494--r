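Package: biofilmq
Title: Quantitative Biofilm Colonization Analysis from Epifluorescence Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify heterogeneous microbial colonization of mineral
    surfaces from tiled epifluorescence micrographs. Provides a seeded synthetic
    tile generator with ground truth, an image-processing chain (percentile
    contrast stretch, unsharp masking, rolling-ball background subtraction,
    thresholding, microcolony labeling) yielding per-tile colony density and
    percent colonized area, a coefficient-of-variation subset procedure that
    certifies sampling sufficiency, hierarchical experiment aggregation with
    Kruskal-Wallis and Dunn post-hoc comparisons, and rule-based screening of
    candidate sugar transporters from tabular homology, membrane-topology and
    operon records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
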