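Package: genecircuit
Title: Autoregulatory Gene-Circuit Models for Pseudotime Expression
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a nonautonomous autoregulatory gene-circuit ordinary
    differential equation to per-gene pseudotime expression trajectories by
    smooth-and-match gradient matching with multi-start bound-constrained
    least squares and an l2-norm penalty on the regulation magnitudes.
    Classifies genes as monostable or multistable from the fixed points of
    the long-time steady-state equation, computes Waddington-style potential
    landscapes in closed form via the Gauss hypergeometric function, and
    scans saddle-node bifurcation diagrams over the inhibitory half-saturation
    constants. Includes a synthetic trajectory generator with known ground
    truth for benchmarking parameter and stability-class recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
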