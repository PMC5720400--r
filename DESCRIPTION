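Package: slitcbct
Title: Multi-Slit Collimator Scatter Reduction Bench for Cone-Beam CT
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully synthetic software bench for studying scatter reduction in
    cone-beam computed tomography (CBCT) with a static multi-slit collimator
    (MSC).  The package models a circular-orbit cone-beam system with a
    source-centred collimator whose open and closed lead septa alternate at
    equal angular intervals, so that two gantry rotations (the collimator
    shifted by one septum interval between them) tile the detector.  It
    provides analytic cylindrical phantoms with 40 keV attenuation
    coefficients, a ray-traced monoenergetic primary projector, a parametric
    smooth scatter model calibrated to a target scatter-to-primary ratio, the
    closed-septum scatter estimation / interpolation / subtraction / merge
    correction, Feldkamp-Davis-Kress (FDK) filtered backprojection, and
    contrast-ratio image-quality metrics, plus MetaImage/TIFF export and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
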