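Package: surfcutr
Title: Surface-Layer Extraction and Epidermal Cell-Contour Analysis for 3D Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts a thin, surface-relative layer of fluorescence signal
    (typically the anticlinal cell walls of the epidermis) from 3D confocal
    Z-stacks by cumulative down-projection of a binarized stack, crops the raw
    signal between two surface-relative depths, and projects the result to a
    2D cell-contour image.  Includes contour-based cell segmentation, a small
    set of cell shape descriptors (area, perimeter, circularity, solidity)
    with the standard small-cell filter, synthetic phantom generators (flat
    sheets, tilted planes, cylinders, hemispheres) with analytic ground truth,
    and a curvature-bias study that quantifies how Z-direction cropping
    underestimates cell area on curved tissue.  Reads and writes uncompressed
    grayscale multi-page TIFF stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    png,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
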