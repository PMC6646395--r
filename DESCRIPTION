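Package: stngpe
Title: Closed-Loop Deep Brain Stimulation in a Conductance-Based STN-GPe Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a heterogeneous subthalamic nucleus (STN) - external
    globus pallidus (GPe) network of conductance-based bursting neurons and
    four closed-loop deep brain stimulation modes: continuous and adaptive
    high-frequency DBS and continuous and adaptive pulsatile linear delayed
    feedback. Includes charge-balanced biphasic pulse-train synthesis with an
    interphase gap, an online resonant filter for the local field potential,
    a Kuramoto-type order parameter computed from burst-onset phases,
    demand-controlled on/off gating with hysteresis thresholds, and
    percentile-threshold burst-length analytics, together with protocol
    averaging over ramp schedules and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
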