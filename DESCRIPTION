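Package: bdcoal
Title: Birth-Death and Coalescent Models of Pairwise Coalescence Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact and approximate models of the time to coalescence of two
    lineages sampled from an exponentially growing population. Implements the
    constant-rate birth-death (BD) process in closed form (Kendall extinction
    and one-lineage probabilities, survival-conditioned expected population
    size with its 'push of the past', origin-time inversion, and the exact
    pairwise coalescent-time distribution), the deterministic
    exponential-growth coalescent (CD) and its survival-conditioned variant
    (CDN), and a stochastic coalescent (CS) that samples coalescence times
    along Gillespie-simulated BD population trajectories. Includes an
    event-driven forward simulator for BD trajectories and full genealogies,
    and an experiment driver that overlays the four cumulative distributions
    across a grid of basic reproductive numbers and population sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
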