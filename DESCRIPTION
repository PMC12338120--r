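Package: gpcn
Title: Graph Prolongation Convolutional Networks for Coarse-Grained
    Molecular Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale ensembles of graph convolutional networks (GPCN and
    adaptive A-GPCN) coupled by spectrally optimized prolongation operators,
    together with the linear graph diffusion distance used to compute those
    operators, multigrid-style training schedules, baseline ensemble models
    (plain ensembles, N-GCN, DiffPool), and a coarse-grained harmonic
    spring-lattice simulator of a 13-protofilament microtubule that generates
    per-monomer potential-energy training data under bending load.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
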