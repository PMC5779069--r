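Package: swcx
Title: Multi-Signal and Time-Varying Extensions of the SWC Neuronal
    Reconstruction Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write, validate and manipulate digital neuronal
    reconstructions in the classic SWC format and its two extensions: ESWC,
    which appends per-compartment statistics (fraction of voxels above
    threshold, their mean intensity and standard deviation) for any number of
    secondary imaging channels, and SWCX, which encodes a time series of
    morphologies in a single table with per-time-point event codes for
    extension, local scaling, rotation/deformation, retraction and
    re-emergence of branches. Includes the frustum voxel-assignment algorithm
    that quantifies multi-channel image stacks over a reconstruction, a
    renderer exporting internal/external frustum geometry, a synthetic
    generator of morphologies, painted image stacks and scripted dynamic
    event series for end-to-end verification, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
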