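Package: sfdepth
Title: In Silico Training for Deep-Learning Fluorescence Depth Mapping with
    Spatial Frequency Domain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic "iceberg" tumor shapes (cylinders, spherical
    harmonics, and composite spherical harmonics), simulates calibrated
    reflectance and fluorescence image stacks under sinusoidally patterned
    illumination using a diffusion-theory forward model with a first-Born
    perturbation treatment of the fluorophore, recovers per-pixel absorption
    and reduced scattering by two-frequency lookup-table inversion, and trains
    a two-arm convolutional network that maps the resulting images to
    per-pixel tumor depth and fluorophore concentration. Includes the
    evaluation statistics and camera-image preprocessing chain needed to apply
    the trained network to phantom measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
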