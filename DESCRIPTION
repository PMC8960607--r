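Package: strutsim
Title: Mechanics-Dependent Osteochondral Defect Repair with Degradable Strut Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of mechanics-dependent tissue differentiation in an
    osteochondral defect implanted with a degradable polymer scaffold of strut-like
    architecture. Couples an axisymmetric Biot poroelastic finite-element stage, a
    mechanoregulation rule based on octahedral shear strain and fluid velocity,
    lattice cell-population dynamics with mesenchymal stromal cell diffusion, and
    four hydrolytic scaffold-degradation modalities (surface erosion, linear bulk,
    autocatalytic bulk, exponential bulk) with analytic degradation milestones and
    scaffold-stiffness trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
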