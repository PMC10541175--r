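Package: granulearn
Title: Task-Dependent Coding Levels in Cerebellum-Like Expansion Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analytic theory of learning in cerebellum-like
    expansion-layer networks. Generates synthetic learning tasks (random
    categorization, Gaussian-process targets on the sphere, two-joint arm
    forward dynamics, vestibulo-ocular reflex tuning curves), builds granule
    cell-like expansion layers with controlled coding level and realistic
    sparse excitatory connectivity, fits Purkinje cell-like readouts (least
    squares, ridge, nonnegative, online climbing-fiber rule), and predicts
    generalization error analytically from the spherical-harmonic
    eigendecomposition of the expansion-layer kernel. Provides config-driven
    experiment drivers for coding-level and architecture sweeps with seeded
    replication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
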