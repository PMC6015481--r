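Package: curvesearch
Title: Query-by-Curve Search of Time-Series Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Search time-series gene expression matrices for genes matching a
    user-supplied curve. A hand-drawn polyline (or a predefined pattern, or an
    existing gene's profile) is resampled onto the experiment's time points and
    scored against every gene by Pearson correlation, in three modes: similar
    (brush), opposite (contrast) and time-shifted (integer lags up to +/-6).
    Includes quality filtering of expression matrices (missing values, low
    Shannon entropy), k-means profile clustering as a comparison baseline,
    result views (ranked table, capped heat map, query-centred correlation
    network with Cytoscape and GraphML export), and a synthetic time-course
    generator with planted co-expressed, inverted and lagged gene families for
    ground-truth benchmarking.
License: MIT + file LICENSE
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
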