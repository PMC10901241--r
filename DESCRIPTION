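Package: pausim
Title: Photoacoustic/Ultrasound Dual-Modality Imaging Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and reconstruction toolkit for photoacoustic and
    ultrasound (PA/US) dual-modality imaging of fiducial marker clips.
    Generates synthetic marker-clip and tissue phantoms, simulates
    band-limited photoacoustic and monostatic pulse-echo ultrasound channel
    data with noise and common-mode interference models, reconstructs bipolar
    images by delay-and-sum beamforming with angular weights for linear and
    half-ring array geometries (including multi-angle joint reconstruction
    and 3D volume assembly), and renders bipolar colormaps, maximum intensity
    projections, and purple/cyan dual-modality fusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    EBImage,
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
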