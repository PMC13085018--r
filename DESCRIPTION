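Package: dipolesep
Title: Precision Bounds for Separation Estimation of Freely Rotating
    Dipole Emitters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Numerical framework for computing the classical Cramer-Rao
    bound of optical detection schemes and the quantum Cramer-Rao bound
    for estimating the separation of two freely rotating dipole emitters
    (fluorophores). Implements a vectorial dipole point spread function
    model with refractive-index mismatch and supercritical-angle
    fluorescence, five detection methods built from direct detection and
    image-inversion interferometry (SLIVER), including a
    polarization-sorted scheme that routes the azimuthal component of the
    dipole radiation through the interferometer (Polar-SLIVER), and a
    reduced-subspace computation of the quantum Fisher information of the
    two-emitter one-photon state. Practical degradations (chromatic
    vortex wave plate, finite detection bandwidth, background,
    misalignment, interferometer split-ratio and phase errors) are
    configurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
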