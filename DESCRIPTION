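Package: purkinjelca
Title: Objective Measurement of Ocular Longitudinal Chromatic Aberration
    from Purkinje-IV Spot Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the longitudinal chromatic aberration (LCA) of the
    anterior eye from fourth Purkinje image (PIV) spot patterns recorded
    under two LED pulse bands (blue 440-480 nm, red 580-640 nm). The
    pipeline segments the iris with a circle Hough transform, isolates the
    dim PIV spots by intensity banding and connected-component noise
    removal, locates the four spots with a small-radius Hough pass and
    pixel-sum centroids, converts spot displacements to Hartmann-test
    wavefront slopes, reconstructs low-order Zernike coefficients by a
    closed-form four-point modal least squares, and converts the per-band
    defocus difference to diopters. A synthetic anterior-segment image
    simulator with known injected wavefronts provides ground truth so the
    whole pipeline is testable without real eye data; the Atchison
    chromatic-difference-of-refraction model supplies a literature
    reference value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
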