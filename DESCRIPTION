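Package: cprnet
Title: Common-Pool Resource Games on Information Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of common-pool resource extraction by
    boundedly rational users embedded in skewed-degree information networks.
    Agents observe only their network neighbours, forecast others' extraction
    with a menu of switching heuristics, and choose high- or low-effort
    extraction through a degree-sharpened logistic rule while the resource
    co-evolves with aggregate effort. The package provides the
    preferential-attachment network generator with controllable degree
    skewness, the environment-dependent game in three equivalent
    parameterizations with a full-information-equilibrium solver, a fast
    compiled simulation engine with a pure-R reference implementation,
    ensemble and sweep analytics (bistability classification, degree-effort
    sorting, majority-illusion index, impact-inequality collapse), and the
    replicator-dynamics analytical companion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
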