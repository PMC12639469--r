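Package: flashPBS
Title: Transmission Pencil-Beam-Scanning Planning and FLASH Dose-Rate
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale treatment-planning and ultra-high-dose-rate (UHDR)
    quantification pipeline for transmission (shoot-through) pencil beam
    scanning with 250 MeV protons and very-high-energy electrons (VHEE,
    150/200 MeV). Provides synthetic phantoms emulating four clinical
    geometry classes, analytic transmission pencil-beam kernels, spot
    placement by centroidal Voronoi tessellation with border spots,
    sparse dose-influence matrices on a precomputed spot grid with
    bilinear column interpolation, nonnegative spot-weight (and optional
    position) optimization against scorecard objectives, delivery-time
    models for a scanned continuous proton beam and a pulsed VHEE linac,
    per-voxel pencil-beam-scanning (PBS) dose-rate maps, DVH/DRDVH
    curves, standard plan metrics, and the FLASH index FI(X Gy, Y Gy/s)
    with threshold-robustness scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
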