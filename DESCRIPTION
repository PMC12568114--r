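Package: ddmr
Title: Dynamic Data Management for Wearable Exercise Recommender Retraining
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for keeping personalized exercise recommenders trained on
    wearable sensor logs up to date as data drift accumulates. Implements a
    dynamic data management pipeline: similarity-based reduction of redundant
    historical exercise sessions (statistical summarization, PCA embedding,
    approximate nearest-neighbour search with exact cosine verification),
    a model-aware feature-weight controller fitted by bi-level optimization,
    versioned packaging of training datasets with lineage metadata, and a
    staged retraining protocol with top-K recommendation metrics (NDCG, F1@K)
    and heart-rate prediction error (MAE, RMSE). Includes a synthetic cohort
    generator with controllable session redundancy and channel drift so the
    full pipeline can be exercised and tested without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
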