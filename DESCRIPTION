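Package: cowordcast
Title: Background-Enhanced Co-Word Trend Forecasting for Biomedical Literature
Version: 0.1.0
Authors@R:
    person("cowordcast", "developers", email = "cowordcast@example.org",
           role = c("aut", "cre"))
Description: Builds time-binned co-occurrence matrices of artificial-intelligence
    and biomedical keywords from dated abstract corpora, orders the keyword axes
    by agglomerative clustering of word embeddings so that semantically similar
    terms are adjacent, and forecasts each cell's future co-occurrence count from
    the spatial window of its neighborhood in the previous time bin using
    pluggable regression backends. Includes ranked trend tables (proportion of
    publications, percentage growth), recurrent multi-step forecasting with
    R-squared traces, a synthetic corpus/tensor generator with known ground-truth
    dynamics, heatmap and projection plotting, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
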