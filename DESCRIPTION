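Package: natind
Title: Adaptation by Natural Induction in Viscoelastic Spring Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of point masses in a 2D plane joined by
    viscoelastic (Maxwell) springs. Overdamped relaxation of mass positions
    performs physical optimisation of the elastic energy, while slow creep of
    the plastic springs' natural lengths performs unsupervised physical
    learning. Under repeated random disturbances of the positions, the
    feedback between the two timescales enlarges the attractor basins of
    low-energy configurations, so the system discovers exceptionally good
    solutions to its own frustration problem and to external problems encoded
    in non-plastic problem springs, including continuous elastic problems and
    spin-glass/MaxCut instances. Provides network and problem generators, a
    compiled settling engine with a guaranteed energy-descent property,
    per-equilibrium creep updates, end-to-end experiment protocols, and
    measurement assays (resettle energy, PCA embeddings of equilibria,
    attractor clustering, log-energy standard scores, neutrality checks, and
    binarised spin-glass scoring).
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
    igraph,
    optparse
Config/testthat/edition: 3
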