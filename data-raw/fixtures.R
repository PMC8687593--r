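# Generates the edge-list fixtures shipped under inst/extdata/.
# Run from the package root: Rscript data-raw/fixtures.R
#
# The three theoretical structures are deterministic. The two
# empirically-informed structures are SYNTHETIC stand-ins built with the
# motif-biased generator (reciprocity + buying-centralization biases observed
# in real fish trade networks): 16 traders, 21 edges each, at least one fully
# isolated trader, and the documented dealer-count contrast (6 vs 12) with
# even dealer counts so balanced region allocation is feasible. The seeds
# below were selected (by the search loop at the bottom, commented) as the
# first ones whose realized draws satisfy those structural constraints.

library(fishtradenet)

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_edge_list(make_absent(16), file.path(out, "absent.edges"),
                comment = "theoretical structure: 16 isolated sellers (absence of network)")
write_edge_list(make_pairs_across(16), file.path(out, "pairs_across.edges"),
                comment = c("theoretical structure: 8 reciprocal cross-region dealer pairs",
                            "traders T01-T08 belong to region 1, T09-T16 to region 2"))
write_edge_list(make_fully_connected(16), file.path(out, "fully_connected.edges"),
                comment = "theoretical structure: fully connected, 240 directed edges")

fixture_ok <- function(net, n_dealers) {
  deg_in <- igraph::degree(net$graph, mode = "in")
  deg_out <- igraph::degree(net$graph, mode = "out")
  sum(trader_types(net) == "dealer") == n_dealers &&
    any(deg_in + deg_out == 0) &&          # one isolated trader
    n_edges(net) == 21L
}

gen <- function(seed, dealer_fraction) {
  set.seed(seed)
  make_motif_biased(16, n_edges = 21, dealer_fraction = dealer_fraction,
                    reciprocity_weight = 6, centralization_weight = 0.3)
}

find_seed <- function(dealer_fraction, n_dealers, from = 1) {
  for (seed in from:(from + 5000)) {
    if (fixture_ok(gen(seed, dealer_fraction), n_dealers)) return(seed)
  }
  stop("no seed found")
}

seed_emp <- find_seed(6 / 16, 6)    # mixed types: 6 dealers, 10 sellers
seed_md <- find_seed(12 / 16, 12)   # same edge count, twice the dealers
cat("seeds: empirical_sim =", seed_emp, " more_dealers =", seed_md, "\n")

write_edge_list(
  gen(seed_emp, 6 / 16), file.path(out, "empirical_sim.edges"),
  comment = c("synthetic stand-in for an empirically informed mixed network",
              "motif-biased generator: n=16, 21 edges, 6 dealers / 10 sellers,",
              sprintf("reciprocity_weight=6, centralization_weight=0.3, seed=%d", seed_emp))
)
write_edge_list(
  gen(seed_md, 12 / 16), file.path(out, "more_dealers.edges"),
  comment = c("synthetic stand-in for the same-density network with more dealers",
              "motif-biased generator: n=16, 21 edges, 12 dealers / 4 sellers,",
              sprintf("reciprocity_weight=6, centralization_weight=0.3, seed=%d", seed_md))
)
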