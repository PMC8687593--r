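Package: fishtradenet
Title: Agent-Based Simulation of Regional Fish Trade Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weekly-step agent-based simulator of dealer/seller trade networks
    coupled to logistic (Gordon-Schaefer) fish stocks in two fishing regions.
    Traders allocate fishing effort between two non-substitutable species by
    balancing demand-driven and catch-per-unit-effort-driven heuristics,
    request and trade fish over a directed network, and sell to two final
    markets whose demand is calibrated to maximum sustainable yield. Includes
    network generators (absent, pairs-across, fully connected, Erdos-Renyi,
    motif-biased), a direction-adapted E-I index of spatial connectivity,
    seasonality and catch-variability scenarios, batch experiment runners, and
    outcome metrics for fish scarcity, stock exploitation and individual
    trader supply.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
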