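Package: herdsync
Title: Behavioral Synchrony Analysis for Scan-Sampled Animal Groups
Version: 0.1.0
Authors@R: person("Herdsync", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing activity synchronization in social ungulate
    groups observed by instantaneous scan sampling. Provides a validated data
    model for scan records with focal animals, nearest-neighbour ranks and
    categorical distances; group synchrony degree and threshold summaries;
    Fleiss' multi-rater kappa on complete scans; dyadic observed synchrony
    against an independence null (sum of behaviour-proportion products) with a
    paired t-test; foraging-activity threshold filtering; nearest-neighbour
    versus random-conspecific synchrony; binary affiliation and winner-loser
    matrices with randomized Elo dominance ranks; the accompanying regression
    models (beta GLM, binomial GLMMs, dyadic LMMs with crossed random effects
    and Satterthwaite single-term deletions); and a seeded agent-based herd
    simulator so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
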