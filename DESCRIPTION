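Package: viaspace
Title: Glocal Exploration of Viable Parameter Regions in Gene Circuit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers, clusters and measures viable parameter regions of
    dynamical gene regulatory network models. A genetic algorithm harvests an
    initial viable set from the full biochemical parameter space, local
    Gaussian sampling directed by principal components refines each region,
    the gap statistic with K-means splits poorly connected regions, and
    Monte-Carlo integration over PCA-aligned bounding boxes turns region
    volumes into a robustness measure. Ships deterministic (stiff ODE) and
    stochastic (Gillespie) simulators for three benchmark circuits: the
    repressilator, the AC-DC circuit and an edge-triggered master-slave
    D flip-flop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
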