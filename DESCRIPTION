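Package: neurocable3d
Title: Three-Dimensional Cable Equation Simulator with Ephaptic Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-volume simulator for the three-dimensional cable equation:
    coupled intra- and extracellular Laplace problems on labeled tetrahedral
    meshes with an active Hodgkin-Huxley membrane, chemical synapses and
    ephaptic feedback through the extracellular potential. Includes programmatic
    mesh builders (cylinder, sphere, idealized multi-cell networks) with a
    barycentric dual grid, implicit Euler time stepping with Newton iteration,
    a one-dimensional cable reference solver with verification metrics
    (relative L2-in-time error, conduction velocity), and a spherical-harmonics
    multipole analyzer of the extracellular potential that exhibits the
    vanishing current monopole of a resistive-volume cell.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
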