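Package: cd8potts
Title: Multiscale Cellular Potts Simulation of the CD8 T-Cell Immune Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale agent-based simulator of the CD8 T-cell immune
    response in a lymph node. Cells are agents on a two-dimensional Cellular
    Potts lattice; each CD8 T-cell carries a six-variable intracellular
    regulatory network (IL2 receptors, Tbet, Fas, Caspases, Eomes) integrated
    as ordinary differential equations and coupled to a diffusing extracellular
    IL2 field. Stochastic uneven partitioning of molecular content at cell
    division, together with an asymmetric first division, drives
    differentiation into effector and memory fates. The package provides the
    molecular network and its bistability analysis, the IL2 reaction-diffusion
    field, the Potts engine, the differentiation/division/apoptosis rules,
    primary- and secondary-response simulations, an unevenness sweep, and
    calibration distance metrics against reference time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
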