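Package: fftindex
Title: One-Dimensional FFT Autoindexing of Oscillation Diffraction Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Autoindexing of macromolecular diffraction spot lists by the
    one-dimensional fast Fourier transform method. Spot positions from one or
    more oscillation images are mapped to dimensionless reciprocal-space
    scattering vectors via the Ewald sphere construction, candidate real-space
    axes are located by projecting the vectors onto a sampled hemisphere of
    directions and detecting periodicities with a one-dimensional FFT, and a
    crystal basis is chosen by integral-index agreement. The chosen cell is
    Niggli-reduced, classified against the 44 lattice characters with
    distortion penalties, and refined under Bravais-lattice constraints
    against the observed spot positions. Additional tools cover automatic
    intensity thresholds, direct-beam grid searches, iterative multi-lattice
    indexing by integer-index outlier rejection, and a forward
    diffraction-geometry simulator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
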