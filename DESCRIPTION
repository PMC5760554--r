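Package: helixsheet
Title: Tilted Light-Sheet Single-Molecule Microscopy Simulation and 3D Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico single-molecule localization microscope with tilted
    light-sheet illumination and pupil-engineered point spread functions (PSFs),
    together with the analysis pipeline that turns its frame streams into 3D
    super-resolution reconstructions. A scalar-diffraction pupil engine builds
    clear-aperture, double-helix, and tetrapod phase masks and renders PSFs at
    arbitrary defocus; a frame-stream simulator produces blinking emitters on
    3D phantom structures with EM-CCD noise, stage drift, and an interleaved
    single-molecule / fiducial / reactivation acquisition schedule. Analysis
    modules provide double-helix localization via double-Gaussian lobe fitting
    with angle-to-z calibration, tetrapod fiducial tracking over a 6-10 um
    axial range with phase-retrieval pupil calibration, closed-loop axial
    feedback, post-hoc drift correction, axial slice stitching by histogram
    cross-correlation, and rendering with line-scan width measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
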