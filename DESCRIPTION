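Package: molassembly
Title: Constrained Construction of Macromolecular Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Build constrained assemblies of rigid molecular surfaces.
    Replicates a monomer into helical chains from an example pair of
    placements, detects collisions with bounding-volume hierarchies
    (including pose-mode filtering and an n-1 shortcut for internal
    collisions of repeated chains), places objects with penalty-based
    pose physics that permits sliding contact, relaxes spring connectors
    with rest lengths into distance-consistent layouts, and samples
    keyframe animations of pose, color, and grouping. Reads Wavefront
    OBJ surfaces and PDB atomic structures, approximates molecular
    surfaces by a Gaussian-density isosurface, and persists scenes in a
    JSON project format with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
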