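Package: rvdesign
Title: Reaction-Based De Novo Design with a Multi-Label Reaction Class
    Recommender
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Encodes chemical reactions as atom-pair difference vectors
    (reaction vectors) computed from AP2/AP3 topological descriptors,
    builds multi-label training data from classified reactions, trains
    reaction class recommenders (binary relevance, classifier chains, and
    random k-labelset ensembles over pluggable base learners), and uses
    the recommendations to filter which reaction vectors are applied
    during structure enumeration, both in single-step de novo design and
    in a pseudo-retrosynthetic fragment-reassembly mode.  Includes a
    synthetic fixtures generator producing classified, atom-mapped,
    carbon-balanced reaction sets so the whole pipeline can be exercised
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
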