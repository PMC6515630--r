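Package: chromocoil
Title: Finite-Size Coil-Globule Polymer Inference for Epigenetic Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers physical chromatin parameters (interaction energy per Kuhn
    segment, Kuhn lengths in base pairs and nanometers, tetraploid-bundle
    geometry) from per-cell distributions of gyration radii of epigenetic
    domains measured by super-resolution microscopy. Implements a calibrated
    finite-size coil-globule polymer free energy and the distribution of the
    squared radius of gyration it induces, an interacting self-avoiding walk
    Monte Carlo simulator on the cubic lattice used to calibrate the free
    energy coefficients and locate the theta point, an exponential bundle
    correction for unresolved paired chromosomes with convolution and
    deconvolution, Bayesian inference of all parameters with an
    affine-invariant ensemble sampler, power-law scaling analysis, a two-angle
    nucleosome fiber plausibility module, and a synthetic-data generator that
    emulates the statistical design of the study.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
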