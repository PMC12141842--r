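Package: pellimetry
Title: Deformation Mapping, Tensile Mechanics and Morphogenesis Kinetics of
    Bacterial Pellicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of bacterial pellicles (biofilms formed at
    the air-liquid interface) under uniaxial stretching and during
    morphogenesis. Provides particle image velocimetry (PIV) by normalized
    window cross-correlation with subpixel peak refinement and outlier
    validation; reduction of displacement fields to one-dimensional
    deformation profiles with affine and continuous piecewise-linear fits,
    region elongation fractions and mechanical classification; conversion of
    cantilever force-sensor recordings to calibrated force-elongation curves
    with failure detection, elastic stiffness and intercept estimation,
    true-strain correction and length rescaling; and time-lapse kinetics
    (kymographs, expansion-front speeds, wrinkle-wavelength detection, colony
    expansion rates). A seeded synthetic-data generator produces speckle
    image pairs warped by prescribed displacement profiles, force-elongation
    traces with abrupt failure, and time-lapse stacks with moving fronts and
    periodic wrinkles, so the whole chain is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
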