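Package: domscope
Title: Sub-Diffusive Spatial-Frequency-Domain Imaging of Epithelial Backscattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward modelling and analysis tools for fiber-bundle diffuse
    optical microscopy (DOM) of epithelial tissue. Implements Monte Carlo
    photon transport in a semi-infinite turbid medium under oblique fiber
    illumination with numerical-aperture-constrained detection,
    Gegenbauer-kernel (Reynolds-McCormick) and Henyey-Greenstein scattering
    phase functions, spatial-frequency-domain reflectance via a discrete
    Fourier transform of binned exit positions, and penetration-depth
    quantiles of the depth-resolved signal. Also provides the
    structured-illumination image pipeline (dark referencing, software
    binning, Butterworth high-pass filtering, three-phase AC/DC
    demodulation, reference normalisation), a synthetic fiber-bundle
    phase-image and multi-case study generator with known ground truth, and
    a depth-dependent backscattering-ratio diagnostic with threshold
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
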