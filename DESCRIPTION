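Package: phasect
Title: Propagation-Based Phase-Contrast CT: Simulation, Phase Retrieval,
    Reconstruction and Virtual Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for laboratory propagation-based x-ray
    phase-contrast tomography of weakly absorbing specimens such as dried
    brain tissue. Simulates near-field (edge-enhanced) projections of
    brain-like phantoms in cone, inverse and parallel geometries; retrieves
    contrast per projection with the Modified Bronnikov Algorithm (MBA) and
    the Bronnikov Aided Correction (BAC); reconstructs volumes with
    ring-corrected filtered back-projection (parallel Ram-Lak FBP and
    Feldkamp cone-beam FDK) including region-of-interest padding and
    factor-2 binning; and produces virtual-histology sections (MIP/MinIP
    slabs, H&E-like rendering) with threshold-based single-cell
    segmentation and 3D cell statistics.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    igraph,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
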