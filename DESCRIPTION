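Package: tuberecon
Title: Serial-Section 3D Reconstruction and Morphometry of the Eustachian Tube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to rebuild a three-dimensional model of the cartilaginous
    Eustachian tube from serially sectioned, digitized histology. The package
    generates a ground-truth phantom of a helically twisted, multi-compartment
    tube embedded in a block with needle fiducials and reference grooves,
    simulates the cutting and digitization protocol (33 micrometre sections at
    330 micrometre blade spacing, per-slice rigid perturbations, lost
    sections), recovers slice-to-slice alignment from the fiducial tracks by
    least-squares colinearity, registers the assembled stack to a tomographic
    reference volume with closed-form rigid landmark registration, profiles
    per-compartment cross-sectional area and circumference along the tube
    axis, estimates the helical torsion of the tube cartilage from per-section
    principal-axis orientations, and exports compartment surfaces as binary
    STL meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
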