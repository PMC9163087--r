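Package: rdnudge
Title: Echo-Chamber Opinion Dynamics and the Random Dynamical Nudge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulators for two opinion-dynamics models that form
    echo chambers: an activity-driven temporal-network model with homophilic
    interactions, and a selective social-influence model with message screens,
    reposting and network rewiring. Implements the random dynamical nudge (RDN)
    intervention family, in which each agent receives a stochastic input built
    from randomly sampled peer opinions, together with the polarization metrics
    (peak distance, peak counting, nearest-neighbour mean opinion, in-degree
    summaries) used to evaluate prevention and depolarization of echo chambers.
    Includes a config-driven experiment runner with seeded parameter sweeps and
    tidy results.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
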