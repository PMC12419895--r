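Package: pilgrimsim
Title: Emergence of Collective Ritual as an N-Person Assurance Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models how a costly collective ritual such as pilgrimage can
    emerge in a population where nobody practises it yet. Provides the
    analytic N-person assurance (stag hunt) game with threshold payoffs,
    binomial expected fitnesses, replicator dynamics and equilibrium/basin
    analysis, together with an agent-based simulator in which agents hold
    Gaussian beliefs about each strategy's payoff, choose by sampling those
    beliefs, and update them in a Bayesian fashion from both their own
    outcomes and a randomly observed demonstrator. Because agents add
    frequency-independent environmental noise to their coordination payoffs,
    lucky draws can be misread as miracles and seed the social strategy.
    Includes the three-visit attendance convention, site-serving and general
    positivity transmission biases, full factorial parameter sweeps, tidy
    summaries and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
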