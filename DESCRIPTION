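Package: forageDDM
Title: Drift-Diffusion Models of Patch-Leaving Foraging Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates patch-leaving foraging decisions as a coupled stochastic
    system: an exponential moving-average estimate of the net energy rate
    available from the environment, and a drift-diffusion patch decision
    variable driven by stochastic (Poisson) food rewards from depleting
    patches.  Provides a marginal-value-theorem analytics layer (optimal
    residence times, decision thresholds, strategy drift rates, first-order
    sensitivity predictions, and a satisficing-utility fixed point), a fast
    compiled session simulator with burn-in and full-cycle averaging, a
    Crank-Nicolson Fokker-Planck solver for first-passage (patch-leaving)
    time distributions, and a configuration-driven command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
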