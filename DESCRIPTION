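Package: avflow
Title: Image-Based Computational Hemodynamics for Murine Arteriovenous
    Fistulae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for magnetic-resonance-image-based
    computational fluid dynamics of murine arteriovenous fistulae and
    other small vessels. Generates synthetic black-blood image phantoms
    of idealized artery-vein junctions, segments the lumen by seeded
    intensity thresholding, reconstructs and smooths a watertight
    triangulated lumen surface, builds a labeled voxel volume mesh,
    extracts centerlines and perpendicular cross-sectional area
    profiles, solves pulsatile incompressible laminar Newtonian flow
    with a SIMPLE finite-volume scheme, and computes wall and
    volumetric hemodynamic metrics (wall shear stress and its spatial
    gradient, oscillatory shear index, vorticity, helicity,
    Q-criterion) with cycle and segment averaging plus mesh and
    time-step independence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
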