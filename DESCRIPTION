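Package: foldpath
Title: Optimal-Control Prediction of Protein Folding Routes on Gaussian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the time-ordered sequence of native-contact formation of a
    protein from its native structure alone. A coarse-grained C-alpha Gaussian
    network is driven toward the native state by an infinite-horizon linear
    quadratic regulator whose state weight is rebuilt each sampling interval
    from the dynamically measured contact map; the synthesized feedback gain
    decomposes into a zero-row-sum harmonic spring matrix plus a uniform
    native-state anchor. Includes PDB C-alpha input/output, contact-map and
    graph-Laplacian construction, an algebraic Riccati solver, the
    optimization-simulation folding engine, folding observables (fractional
    cluster contacts, contact initiation times, radius of gyration, effective
    contact order), and synthetic native-structure fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
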