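Package: plsmc
Title: Protein Complex Detection in PPI Networks by Penalized Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies (possibly overlapping) protein complexes from a
    protein-protein interaction (PPI) network by estimating nonnegative
    protein-to-complex propensities whose pairwise products approximate
    neighborhood-overlap interaction weights. The penalized least-squares
    objective is minimized with multiplicative updates under random
    restarts; large networks are first decomposed into subnetworks by
    recursive greedy modularity clustering. Includes the standard
    complex-prediction evaluation metrics (f-measure, Sn/PPV/Acc, maximum
    matching ratio and their composite), a planted-complex synthetic
    network generator, readers and writers for edge-list/SIF networks and
    one-complex-per-line catalogues, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
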