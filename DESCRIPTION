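Package: hydrosite
Title: Binding-Site Probe Fields, Explicit Water Networks and Toy Metadynamics for Pocket Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for energetic analysis of protein binding sites at desk
    scale. Computes GRID-style molecular interaction fields for water (OH2),
    aromatic carbon (C1=), methyl (C3), hydrophobic (DRY) and the composite
    lipophilic CRY probe on a lattice; detects hotspots and pocket surfaces;
    builds, relaxes and scores explicit three-site water networks with a
    happy/unhappy free-energy classification against a bulk-solvent
    reference; assesses subpocket druggability from adjacent lipophilic and
    polar hotspots occupied by unhappy waters; and estimates binding free
    energies on analytic toy landscapes with an adiabatic-bias ratchet
    binding path followed by shared-hills well-tempered metadynamics over a
    path collective variable. Ships a synthetic fixture generator (toy
    cavity receptors with planted sites, rigid toy ligands, bulk water
    boxes, double-well landscapes with quadrature ground truth) so every
    stage is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
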