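Package: dcgs
Title: Divide-and-Conquer Global Stabilization of Boolean Molecular Networks
Version: 0.1.0
Authors@R: person("DCGS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for global stabilizing control of synchronous Boolean
    models of molecular regulatory networks. Identifies minimal node sets
    whose persistent fixation drives every initial state into a desired
    point attractor by combining strongly-connected-component hierarchy
    decomposition, exhaustive minimal feedback-vertex-set enumeration and
    canalizing-effect percolation (the DCGS framework), with brute-force
    control-kernel search and feedback-vertex-set control as validation
    baselines. Includes a parser/writer for BoolNet 'bnet' rule files,
    exhaustive and hierarchical attractor computation with basin ratios,
    a generator of biological random Boolean networks (power-law
    out-degree, Poisson in-degree, canalizing update rules), and a
    command-line benchmark harness comparing the control frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
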