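Package: patchdyn
Title: Patch-Scale Event Dynamics of Habitat Loss on Percolation Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates dynamic neutral landscape models on toroidal
    triangular (six-neighbour) and square (von Neumann) lattices at
    constant habitat density, classifies every single-site change into one
    of six elementary patch events (formation, loss, enlargement,
    shrinkage, coalescence, splitting), and derives event-probability
    curves over the habitat-loss gradient, percolation-threshold estimates
    from torus-wrapping clusters, the four transitions delimiting five
    phases of landscape degradation, and the amplification factor of
    effective habitat loss for organisms requiring a minimum viable patch
    size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
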