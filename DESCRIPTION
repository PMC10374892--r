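Package: igisml
Title: Closed-Loop Simulation and Control for Image-Guided Maskless Lithography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prototyping microfluidic devices by image-guided in-situ
    maskless lithography (IGIs-ML). A finite-difference reaction-diffusion
    simulator of free-radical UV photopolymerization stands in for the physical
    device, and the control layer runs against it: rasterization of vector
    designs to DMD projector masks, uniform and graded illumination fields,
    annular-mask greyscale edge tracking with cutoff and two-peak triggering,
    optical proximity correction of polygon corners via squircle transforms,
    iterative tip/trench dynamic shape correction, DXF design compilation into
    tiled projection units with critical-distance slicing and flush-flow
    scheduling, deterministic lateral displacement (DLD) array generation, and
    metrology (radial profiles, RMS roughness, diameter broadening series,
    row-shift recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
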