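Package: ergraph
Title: Graph Signal Processing of Transient Electrophysiological Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transforms short transient electrophysiological waveforms, such
    as the light-adapted electroretinogram, into weighted undirected graphs
    by amplitude quantization and temporal adjacency. Extracts nine
    topological and spectral graph features (total load and harmonic
    centrality, maximal clique count, diameter, radius, average clustering,
    average path length, algebraic connectivity, density) and classifies
    diagnostic groups through a subject-wise nested cross-validation
    pipeline with minority oversampling. Includes five alternative
    time-series-to-graph constructions (visibility graph, recurrence
    network, k-nearest-neighbour graph, epsilon-ball graph, ordinal
    partition network), nonparametric group-difference statistics
    (Kruskal-Wallis, Dunn's post hoc, Cliff's delta), and a parametric
    synthetic waveform generator so the whole pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    randomForest,
    xgboost,
    e1071,
    class,
    nnet,
    rpart,
    jsonlite,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
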