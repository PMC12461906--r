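Package: membuildr
Title: Curvature-Aware Construction of Coarse-Grained Membrane Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds simulation-ready coarse-grained membrane structures of
    arbitrary shape. Triangulated surfaces (a FreeDTS-style .tsi dialect or
    OBJ) are oriented, cut if nonorientable, and discretized into per-leaflet
    point sets carrying areas, normals and principal curvatures; lipids and
    proteins are then organized laterally by Boltzmann-weighted curvature
    preference, geodesic or Euclidean domains, pores and edge-specific
    placement; finally lipid templates are instantiated into GROMACS
    structure (.gro) and topology (.top) files, with wall-bead scaffolds and
    a fast tiling solvation tool. Analytical flat, sine, vesicle and
    cylinder membranes are supported directly, and deterministic synthetic
    fixtures (icosphere, cylinder, torus, Moebius strip, sine sheet) make
    the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
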