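Package: traplinr
Title: Agent-Based Simulation of Trapline Foraging in Central-Place Pollinators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time, multi-agent simulation of central-place pollinators
    (bees) foraging on continuously renewing nectar sources. Route learning is
    modelled as per-transition reinforcement learning (Q-learning) with softmax
    decision-making and a working memory that inhibits returns to recently
    visited feeding sites. The package generates uniform and patchy
    environments, runs single- and multi-forager simulations, computes a
    sliding-window sequence-similarity index and per-bout foraging success,
    and provides reproducible parameter-sweep experiments over site spacing,
    nectar renewal duration, working-memory span and colony size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
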