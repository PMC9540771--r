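Package: phenovir
Title: Host Phenology and the Evolution of Parasite Virulence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying virulence evolution in seasonal,
    obligate-killer parasites of hosts with non-overlapping generations.
    Provides exact within-season solutions of the resident
    delay-differential system describing host emergence, infection and
    progeny release, an independent numerical oracle, the between-season
    map with its resident equilibrium and persistence criterion,
    evolutionary invasion analysis (selection gradients, singular
    strategies, ESS and convergence-stability classification, pairwise
    invasibility plots) for the incubation delay with and without
    transmission-virulence trade-offs, a seeded individual-based
    stochastic validator, and parameter-sweep experiments over season
    length and host emergence synchrony.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
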