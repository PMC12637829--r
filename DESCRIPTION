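Package: fibriltools
Title: Geometry, Stability and Force-Spectroscopy Analysis of Amyloid
    Fibril Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structural analysis of helical amyloid fibril
    models: layer ordering and ordered-core extraction from PDB/mmCIF
    coordinates, helical rise/twist/crossover and handedness, layer-plane
    warping statistics, solvent-accessible surface areas with an atomic
    solvation parameter model of per-layer stabilization free energy,
    chaperone-binding-site accessibility metrics, and worm-like-chain
    analysis of single-molecule optical-tweezers force-extension curves
    with unfolding-rip detection. Includes seeded generators for
    idealized cross-beta fibril coordinates and quasi-static
    force-extension curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
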