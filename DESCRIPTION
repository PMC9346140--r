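Package: gazemdp
Title: Markov Decision Process Modeling of Eye Movement for Situation
    Awareness in Dynamic Interactive Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the eye movement of experienced operators in dynamic
    interactive tasks (such as instrument flight) as a finite-horizon
    Markov decision process over a binary situation-awareness state, one
    bit per area of interest (AOI). Information in each AOI updates
    stochastically at a rate coded by its bandwidth (expectancy), and the
    reward for fixating an AOI whose information is unknown is the
    value of the subtasks it serves weighted by subtask-AOI relevance.
    Provides exact transition and reward tables, an optimal fixation
    policy by backwards induction, a one-step greedy baseline, seeded
    Monte Carlo scanpath simulation with situation-awareness rasters and
    delay-to-notice extraction, and a validation battery that compares
    predicted fixation and shift probabilities against observed gaze
    distributions for eight flight-display conditions shipped as
    fixtures.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
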