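Package: webrds
Title: Web-Based Respondent-Driven Sampling: Simulation, Intake Cleaning,
    and Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and auditing web-based
    respondent-driven sampling (web-RDS) studies of hidden populations,
    such as users of electronic nicotine delivery systems. Includes a
    synthetic-population generator with configurable homophily and
    degree heaping, a coupon-based chain-referral recruitment simulator
    with incentive-dependent participation and fraud injection, a
    multistep intake-cleaning funnel (automatic blocking, email
    similarity heuristics, self-recruitment detection, eligibility and
    consistency screens), deterministic network-size imputation, a
    design-effect sample-size calculator, recruitment-forest
    diagnostics (waves, productivity, convergence, homophily), RDS-II
    reciprocal-degree weighting, and a seed-chain bootstrap for design
    effects.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
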