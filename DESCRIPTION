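Package: tomopick
Title: Layered Annotation Projects and Processing Tools for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Storage-agnostic data model for collaborative cryo-electron
    tomography annotation projects: multiscale chunked tomogram storage
    (OME-Zarr style pyramids with byte-shuffle/LZ4 compression), point
    annotations with full 4x4 particle poses, triangle meshes and 8-bit
    voxel segmentations sharing a common angstrom coordinate frame, and
    static/mutable project layers for conflict-free collaboration.
    Includes import/export for MRC, EM, TIFF, STAR, Dynamo-table and CSV
    formats, an annotation-processing operation suite (pick/segmentation/
    mesh interconversion, Boolean and spatial filtering, connected
    components, skeletonization, convex hulls), a plugin-based command
    line interface with machine-readable introspection, and a synthetic
    fixture generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
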