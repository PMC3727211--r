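Package: mshead
Title: Multiscale Head Models and RF Field Analysis Around Implanted Leads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds two-resolution anatomical label models of the head by
    hierarchical B-spline free-form-deformation (FFD) registration of a
    micro-resolution atlas onto a millimetric head model, embeds a
    four-contact deep-brain-stimulation lead, assigns 128 MHz dielectric
    properties, solves Maxwell's equations with a finite-difference
    time-domain (FDTD) scheme on a graded Yee grid with CPML absorbing
    boundaries, and quantifies local, mass-averaged (1 g / 10 g) and
    whole-head specific absorption rate (SAR) together with electric-field
    differences between coarse and multiscale models.  Includes an
    analytic phantom generator with known ground truth so the whole
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
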