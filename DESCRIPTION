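Package: flypulse
Title: Pulsatile Gene Expression Under Variable Energy Metabolism and
    Compound-Eye Lattice Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic and deterministic simulation of transient
    (pulsatile) expression of a single developmental gene driven by
    primary and auxiliary activators, with kinetic rate constants that
    scale with cellular energy metabolism.  Provides the error-frequency
    and under-expression statistics that quantify the consequence of
    losing auxiliary activators, quasi-random parameter sweeps across
    model variants (linear, gene-copy-bounded, Hill), a
    Delaunay-triangulation disorder metric for ommatidial lattices of
    the insect compound eye, developmental-time expression-dynamics
    smoothing and cross-correlation alignment for eye-disk cell tables,
    and synthetic-data generators with known ground truth for every
    pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    deldir,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
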