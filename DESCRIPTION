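Package: tritroph
Title: Stochastic and Deterministic Dynamics of a Trophically Transmitted
    Parasite in a Predator-Prey System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-species eco-epidemiological system in which a
    parasite is transmitted trophically from an intermediate host (the prey)
    to a definitive host (the predator).  The individual-level reaction
    network (reproduction, competition, infection, predation, death) is
    simulated exactly with the Gillespie stochastic simulation algorithm,
    and its mean-field counterpart, a five-variable ordinary differential
    equation system, is integrated with a stiff-capable solver.  Interior
    (three-species) equilibria are located from a polynomial condition on
    the infected-prey abundance with back-substitution for the remaining
    populations, and a numerical invasion growth rate is computed at the
    parasite-free equilibrium.  Parameter-plane sweeps classify long-run
    outcomes (which species persist, and whether infected or uninfected
    subpopulations dominate within each host), and region boundaries are
    refined by bisection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
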