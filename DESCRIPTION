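Package: preycat
Title: Virtual Predator Foraging Experiments on Prey Categorization
Version: 0.1.0
Authors@R:
    person("preycat", "maintainers", email = "preycat@example.org",
           role = c("aut", "cre"))
Description: Simulates virtual predator-prey foraging experiments that probe
    how the phenotypic diversity (richness and evenness) of a prey community
    shapes the way predators categorize prey as profitable or unprofitable.
    Builds the five experimental training communities and the common test
    community, runs foraging games (pretraining, training with a life bar and
    feedback, feedback-free test trials) for synthetic predator agents
    implementing competing categorization hypotheses (Rescorla-Wagner
    compound-cue learning, key-trait use, capacity-limited memorization,
    random guessing), and analyses the resulting attack records with a
    no-intercept binomial logit model, delta-method trait contrasts,
    Bonferroni-grouped pairwise comparisons, and a split-versus-lumped
    likelihood-ratio test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
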