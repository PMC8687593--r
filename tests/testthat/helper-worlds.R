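# Shared builders for small test worlds.

# Two traders, one per region: T1 (region 1) is a dealer buying from the
# seller T2 (region 2). Used for hand-computed single-week ledgers.
micro_network <- function() {
  trade_network(2L, matrix(c(1L, 2L), ncol = 2))
}

micro_config <- function(scenario = "seasonality", years = 1L, ...) {
  sim_config(network = micro_network(), scenario = scenario,
             traders_per_region = 1L, years = years, replicates = 1L,
             summary_years = 1L, ...)
}

# random small network with an even dealer count, suitable for balanced
# region assignment
random_balanced_network <- function(n = 16L, n_edges = 30L) {
  repeat {
    net <- make_erdos_renyi(n, n_edges, dealer_fraction = 0.5)
    if (sum(trader_types(net) == "dealer") %% 2L == 0L) return(net)
  }
}

# brute-force E-I oracle: plain loop over edges
ei_brute <- function(net, regions, focal = 1L) {
  em <- edge_matrix(net)
  ext <- 0L
  int <- 0L
  for (k in seq_len(nrow(em))) {
    if (regions[em[k, 1L]] == focal) {
      if (regions[em[k, 2L]] == focal) int <- int + 1L else ext <- ext + 1L
    }
  }
  (ext - int) / nrow(em)
}
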