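Package: utslmap
Title: Multi-Scale Acquisition Mapping and Simulation for Ultrathin
    Section Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hardware-independent implementation of the multi-scale
    acquisition workflow used to image ultrathin-section libraries (UTSLs)
    on scanning electron microscopes: full-wafer mapping with automatic
    template-matching section detection and tape-order numbering,
    fiducial-based stage coordinate transforms, pixel-to-stage calibration,
    rigid cross-correlation alignment of section overviews, target-point
    setup with running-average local alignment, wafer-reload registration,
    image-based stage correction, a sparse-sampling image quality metric,
    autofocus/autostigmation strategies, montage tile planning, and
    quality-gated resumable montage acquisition with logging. A built-in
    simulated microscope renders images from a procedural tissue/wafer
    phantom with known ground truth, so the entire pipeline runs and is
    testable without instrument hardware or external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
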