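Package: platescan
Title: Automated Nuclei Counting in Tiled Well-Plate Fluorescence Scans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fluorescently labeled cell nuclei in
    stitched (tiled) scans of multi-well culture plates, such as those
    produced by benchtop imagers that mosaic adjacent fields into one
    image per well. The package locates the circular growth area of each
    well regardless of its position in the frame, masks and contracts it,
    rescues dim nuclear signal with a normalized log contrast transform,
    flattens the tile-seam illumination artifact with a set-wide
    illumination function, and counts nuclei by thresholding with
    diameter gating and optional watershed declumping. Per-well counts
    are aggregated into population-doubling growth curves. A synthetic
    plate-scan generator reproduces the characteristic artifacts of
    stitched scans (well halo, per-tile vignetting, debris, exposure
    variation, well-position jitter, ovoid frame compression) with known
    ground truth, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, EBImage, png, Biobase,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
biocViews: CellBiology, Software, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'config.R'
    'enhancement.R'
    'image_io.R'
    'nuclei.R'
    'pipeline.R'
    'platescan-package.R'
    'quantify.R'
    'utils.R'
    'synthetic.R'
    'well_isolation.R'
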