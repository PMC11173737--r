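Package: hydroshape
Title: Shape-Dependent Hydrophobic Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how hydrophobic interactions depend on the
    geometry of a solute surface. Implements a closed-form hydration
    thermodynamics model (interfacial-water ratio, critical solute radius,
    geometric factor, interfacial-to-bulk energy accounting, and the
    molecular packing-parameter shape rule), geometric hydrogen-bond
    detection with local network classification (DDAA/DDA/DAA/DA/free) and
    interfacial/bulk water partitioning against implicit solute surfaces,
    self-consistent WHAM reconstruction of potentials of mean force from
    umbrella-sampling windows with water-induced decomposition and feature
    (minimum/barrier) extraction, and fully seeded synthetic-data
    generators (parametric solute shapes, water-like packings, harmonically
    biased Metropolis samples from a known free-energy profile, and
    association trajectories with planted interfacial-to-bulk transition
    counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
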