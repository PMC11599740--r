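Package: qualdyn
Title: Qualitative Dynamics of Biological Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logical (Rene Thomas) modelling of biological regulatory
    networks: signed threshold interaction graphs, logical parameter
    tables, asynchronous unitary state transition graphs, attractor and
    fixed-point detection, a CTL (computation tree logic) model checker
    used to identify logical parameter sets compatible with observed
    behaviour, betweenness-centrality based trajectory, cycle and
    bifurcation analysis of state graphs, and a continuous ODE
    translation of logical models with Hill kinetics. Ships a worked
    nine-entity HIF-1/VEGF/GLUT-1 cancer signalling case study with a
    one-command reproduction pipeline, plus generators for random
    networks, parameter tables and kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    igraph,
    jsonlite,
    yaml,
    deSolve,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
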