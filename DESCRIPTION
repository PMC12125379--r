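Package: pwmod
Title: Expected Modularity in Probabilistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and approximate computation of the expected modularity of a
    given clustering of a probabilistic network, i.e. an undirected simple
    graph whose edges carry independent existence probabilities. Implements
    the possible-world partitioning algorithm (PWP) and its fast variant
    (FPWP), which evaluates per-community Poisson-binomial edge-count
    distributions in closed form via the discrete Fourier transform, together
    with a brute-force possible-world enumerator, Monte Carlo sampling,
    probability thresholding and weighted-modularity baselines. Includes
    planted-partition and classical random-graph generators with
    entropy-controlled edge-probability assignment for simulation studies,
    plus readers and writers for plain-text probabilistic edge lists and
    node-community files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
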