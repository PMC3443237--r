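Package: peakclust
Title: Peak-Clustering Group Statistics for MEG Beamformer Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level inference for volumetric MEG beamformer images via
    peak clustering. Each participant's statistic image is compressed to a
    rank-ordered list of local maxima; the smallest confidence ellipsoid
    containing at most one peak per participant is compared against a
    permutation null obtained by shuffling peak ranks, avoiding the
    inhomogeneous-smoothness artefacts that affect voxelwise group tests on
    beamformer output. Includes a single-sphere dipole MEG simulator, an
    LCMV scalar beamformer producing pseudo-t images, an SnPM-style
    variance-smoothed permutation comparator, and a hit/miss simulation
    protocol for benchmarking both methods.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
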