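Package: symdyn
Title: Seasonal Resource-Competition Dynamics of Coral Symbiont Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time optimal-resource simulator for competing
    Symbiodinium (zooxanthellae) populations within a coral host. Four
    symbiont types with Gaussian niche responses to solar insolation and
    sea-surface temperature grow, divide and compete for light under
    seasonal sinusoidal forcing, with per-step stochastic resampling of
    their environmental optima and a thermal-anomaly (bleaching-stress)
    scenario. Includes seasonal-curve fitting from monthly climatologies,
    seeded ensemble runs, symbiont-shuffling summaries, ggplot2 figures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
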