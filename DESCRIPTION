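Package: coexcluster
Title: Coexpression-Network Clustering of Transcriptional Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coexpression networks over differential-expression hit
    lists using a precomputed gene-partner database, scores network
    prediction accuracy (CoRegScore) and gene-set regulation across
    experiments (UpRegScore) with rank-sum statistics, assesses
    significance against random-gene-list null distributions, evaluates
    clusters against genome-wide transcription-factor target rankings, and
    exports Cytoscape-ready network files. Includes a ground-truthed
    synthetic-data generator with planted coexpression modules so every
    stage of the pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
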