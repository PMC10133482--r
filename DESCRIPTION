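Package: squirmtopo
Title: Squirmer Hydrodynamics near Flat and Periodically Structured Walls
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Boundary-integral simulation of a spherical tangential squirmer
    swimming in Stokes flow near no-slip boundaries, using the
    nearest-neighbour regularised Stokeslet method with a two-level
    (coarse traction / fine quadrature) surface discretisation. Supports
    free-space swimming, a half-space wall through a regularised image
    system, and explicitly discretised wall patches carrying singly and
    doubly periodic sinusoidal surface topographies. Provides the
    instantaneous rigid-body mobility and resistance solves, adaptive
    trajectory integration with physically motivated stopping events,
    oscillation diagnostics, and a scenario runner reproducing the
    free-space speed table, the flat-wall stable swimming height, and
    topography-guidance sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
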