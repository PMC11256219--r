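Package: nreflect
Title: Co-Refinement of Multi-Contrast Neutron Reflectometry Data from
    Floating Protein-Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Slab-model analysis of specular neutron reflectometry data from
    self-assembled floating protein-lipid membranes at the gold/water
    interface. Provides an Abeles optical-matrix reflectivity kernel with
    Nevot-Croce and erf-profile microslicing roughness treatments, a
    constrained volume-fraction model of the metal/SAM/water/membrane
    interfacial structure, simultaneous (co-refined) fitting of bare-surface
    and membrane datasets across solvent isotopic contrasts by differential
    evolution and bounded least squares, delayed-rejection adaptive Metropolis
    (DRAM) Markov chain Monte Carlo uncertainty quantification with shortest
    percentile intervals and resampled reflectivity/profile bands, a
    counting-statistics synthetic data generator emulating time-of-flight
    reflectometers, and analytic quartz crystal microbalance (QCM-D)
    penetration-depth and Sauerbrey calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
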