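Package: curvsense
Title: Membrane Curvature Sensing Analysis for Coarse-Grained Bilayer Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for protein localization on substrate-curved
    coarse-grained lipid bilayers. Fits radially averaged membrane height
    profiles with a sigmoid model and derives curvature and radius of
    curvature from its analytic derivatives, computes area- and
    density-normalized radial distribution functions (bulk = 1) of protein
    and lipid species around a central pore, profiles per-residue contacts
    with hydrophobic lipid tails and PIP2 headgroups, and ships a synthetic
    generator that emulates a wafer-curved membrane with curvature-sorted
    PIP2 and proteins driven by competing hydrophobic and electrostatic
    attractions, so every stage is testable without molecular dynamics
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
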