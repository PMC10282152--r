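Package: memwm
Title: Memristor-Based Working-Memory Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a memristor-based spiking neural
    network that realises the dual functional states of working memory:
    sustained neuronal firing (the "focused" state) and activity-silent
    storage in synaptic weights (the "unfocused" state).  Provides a
    nonlinear threshold memristor device model with programming-threshold
    state dynamics, window functions, pulse/sweep protocol drivers,
    device-variability sampling and least-squares parameter fitting; a
    simplified timing-window Hebbian plasticity rule that maps LTP/LTD
    decisions onto SET/RESET programming pulses; a clock-driven
    leaky-integrate-and-fire network with winner-takes-all competition
    between freely-conjunctive neurons and bidirectional plastic coupling
    to feature-selective neurons; and analysis tools for encoding,
    attention and cued retrieval experiments.  All results are returned
    as tibbles and plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
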