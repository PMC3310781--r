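Package: mnpmap
Title: Magnetic Nanoparticle Density Mapping from Magnetomotive Tissue Displacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for quantitative mapping of magnetic
    nanoparticle density in soft tissue from magnetically induced
    displacement. Models the magnetostatics of a Helmholtz/Maxwell coil
    pair (axial closed forms and off-axis elliptic-integral fields),
    solves the static Navier equation on tissue-mimicking phantoms with
    force-loaded inclusions using locking-free structured-grid finite
    elements, and inverts the axial displacement back to a force /
    nanoparticle-density map via the Laplacian approximation, with and
    without the divergence term. Includes coil current-requirement
    calculators, linearity and halo-artifact metrics, and scripted
    end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    pracma,
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    withr
Config/testthat/edition: 3
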