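Package: epulearn
Title: Ensemble Positive-Unlabeled Learning for Disease Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate disease genes from a positive set of
    confirmed disease genes and an unlabeled gene universe, with no negative
    training set. Builds protein-interaction, co-expression and Gene Ontology
    similarity networks, seeds them with phenotype-derived candidate positives
    and distance-derived reliable negatives, propagates signed labels by random
    walk with restart, trains three weighted positive-unlabeled base
    classifiers (weighted k-nearest-neighbour, weighted naive Bayes and a
    multi-level cost-weighted support vector machine), and combines them with
    an ensemble weight vector learned by gradient descent on the squared
    training error. Includes a synthetic-data generator with planted disease
    modules and hidden positives so the full protocol runs end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
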