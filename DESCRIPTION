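Package: neoplasim
Title: Agent-Based Simulation of Tumour Growth and Clonal Evolution on a Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-scale stochastic model of tissue homeostasis and tumour
    growth. Cells with heritable genomes live inside the elements of a
    rectangular grid, share a nutrient and per-gene growth factors by
    relative demand, age on an internal countdown clock, divide, and compete
    by fitness when an element exceeds its carrying capacity. Malignant
    cells mutate and invade neighbouring elements, producing clonal
    evolution, necrotic-core formation and, under cytotoxic treatment
    strategies, accelerated repopulation. Includes experiment presets, a
    replicate runner with mean/SD aggregation, CSV and snapshot writers and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
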