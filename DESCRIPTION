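Package: traitshift
Title: Decomposition of Community-Weighted Mean Trait Variation into
    Species Turnover and Intraspecific Components
Version: 0.1.0
Authors@R:
    person("Plainfield", "Ecology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for partitioning among-site variation in
    community-weighted mean (CWM) plant trait values into species
    turnover, intraspecific trait variation (ITV), and their covariation
    using a sum-of-squares decomposition.  Includes construction of
    total ("specific"), interspecific ("fixed"), and intraspecific CWMs
    from individual-level trait records and relative-cover matrices;
    variance partitioning of environmental regression models with AICc
    stepwise selection; pairwise between-site decomposition with
    distance-decay summaries; Mantel and partial Mantel permutation
    tests on geographic and environmental distance matrices; and a
    seeded synthetic metacommunity generator with known turnover and
    ITV structure for validating every pipeline stage against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
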