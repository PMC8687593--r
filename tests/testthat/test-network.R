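test_that("absent network is all isolated sellers", {
  net <- make_absent(16)
  expect_equal(n_traders(net), 16L)
  expect_equal(n_edges(net), 0L)
  expect_true(all(trader_types(net) == "seller"))
  expect_true(all(out_degree(net) == 0L))
  expect_equal(n_traders(make_absent(2)), 2L)
  expect_error(make_absent(15), "even")
})

test_that("pairs-across network is reciprocal cross-region dealer pairs", {
  net <- make_pairs_across(16)
  regions <- attr(net, "regions")
  expect_equal(n_edges(net), 16L)
  expect_true(all(trader_types(net) == "dealer"))
  em <- edge_matrix(net)
  deg_out <- tabulate(em[, 1], 16)
  deg_in <- tabulate(em[, 2], 16)
  expect_true(all(deg_out == 1L) && all(deg_in == 1L))
  # every edge crosses regions and is reciprocated
  expect_true(all(regions[em[, 1]] != regions[em[, 2]]))
  key <- paste(em[, 1], em[, 2])
  rev_key <- paste(em[, 2], em[, 1])
  expect_true(all(rev_key %in% key))
  expect_equal(ei_index(net, regions), 0.5)

  net4 <- make_pairs_across(4)
  expect_equal(n_edges(net4), 4L)
  expect_error(make_pairs_across(6), "multiple of 4")
})

test_that("fully connected network has all ordered pairs", {
  net <- make_fully_connected(16)
  expect_equal(n_edges(net), 240L)
  expect_true(all(trader_types(net) == "dealer"))
  net2 <- make_fully_connected(2)
  expect_equal(n_edges(net2), 2L)
  # 8/8 split: (64 - 56)/240 = 1/30
  regions <- rep(c(1L, 2L), each = 8)
  expect_equal(ei_index(net, regions), 1 / 30)
})

test_that("Erdos-Renyi generator honours edge count and seller constraint", {
  set.seed(1)
  expect_equal(n_edges(make_erdos_renyi(16, 0)), 0L)
  full <- make_erdos_renyi(16, 240, dealer_fraction = 1)
  expect_equal(n_edges(full), 240L)
  for (i in 1:100) {
    net <- make_erdos_renyi(16, 30, dealer_fraction = 0.5)
    expect_equal(n_edges(net), 30L)
    em <- edge_matrix(net)
    expect_true(all(em[, 1] != em[, 2]))
    expect_false(anyDuplicated(paste(em[, 1], em[, 2])) > 0)
    # at least the 8 non-designated traders have out-degree 0
    expect_gte(sum(out_degree(net) == 0L), 8L)
    expect_true(all(trader_types(net)[out_degree(net) == 0L] == "seller"))
  }
  expect_error(make_erdos_renyi(16, 1000), "infeasible")
})

test_that("Erdos-Renyi draws are reproducible bit-exactly under a seed", {
  set.seed(99)
  a <- make_erdos_renyi(16, 30, dealer_fraction = 0.5)
  set.seed(99)
  b <- make_erdos_renyi(16, 30, dealer_fraction = 0.5)
  expect_identical(edge_matrix(a), edge_matrix(b))
  expect_identical(trader_types(a), trader_types(b))
})

test_that("motif biases raise reciprocity and reduce to uniform at zero", {
  recip_frac <- function(net) {
    em <- edge_matrix(net)
    key <- paste(em[, 1], em[, 2])
    mean(paste(em[, 2], em[, 1]) %in% key)
  }
  set.seed(11)
  n_draws <- 200
  f0 <- replicate(n_draws, recip_frac(make_motif_biased(16, 30)))
  f_er <- replicate(n_draws, recip_frac(make_erdos_renyi(16, 30)))
  # zero weights behave like Erdos-Renyi (3 standard errors)
  se <- sqrt(stats::var(f0) / n_draws + stats::var(f_er) / n_draws)
  expect_lt(abs(mean(f0) - mean(f_er)), 3 * se)
  # strong reciprocity bias produces strictly more reciprocal dyads
  f_hi <- replicate(n_draws, recip_frac(make_motif_biased(16, 30,
                                                          reciprocity_weight = 50)))
  expect_gt(mean(f_hi), mean(f0))
  expect_gt(stats::t.test(f_hi, f0, alternative = "greater")$statistic, 5)
  # saturation: all pairs used regardless of weights
  sat <- make_motif_biased(4, 12, reciprocity_weight = 7,
                           centralization_weight = 3)
  expect_equal(n_edges(sat), 12L)
})

test_that("centralization bias concentrates buying relationships", {
  set.seed(12)
  gini_out <- function(net) stats::sd(tabulate(edge_matrix(net)[, 1], 16))
  g0 <- replicate(200, gini_out(make_motif_biased(16, 30)))
  g_hi <- replicate(200, gini_out(make_motif_biased(16, 30,
                                                    centralization_weight = 5)))
  expect_gt(mean(g_hi), mean(g0))
})

test_that("region assignment balances counts and trader types", {
  set.seed(3)
  net <- make_fully_connected(16)
  for (i in 1:20) {
    regions <- assign_regions(net, 8)
    expect_equal(sum(regions == 1L), 8L)
    expect_equal(sum(regions == 2L), 8L)
  }
  # mixed-type network: equal dealers per region in every draw
  mixed <- random_balanced_network()
  ty <- trader_types(mixed)
  for (i in 1:50) {
    regions <- assign_regions(mixed, 8)
    expect_equal(sum(ty == "dealer" & regions == 1L),
                 sum(ty == "dealer" & regions == 2L))
  }
  # odd dealer count is rejected
  odd <- trade_network(4L, matrix(c(1L, 2L), ncol = 2))
  expect_error(assign_regions(odd, 2), "odd")
})

test_that("E-I index agrees with brute-force link counting", {
  net <- make_pairs_across(16)
  expect_equal(ei_index(net, attr(net, "regions")), 0.5)
  full <- make_fully_connected(16)
  regions <- rep(c(1L, 2L), each = 8)
  expect_equal(ei_index(full, regions), 1 / 30)

  set.seed(21)
  for (i in 1:100) {
    rn <- make_erdos_renyi(16, sample(5:60, 1), dealer_fraction = runif(1, 0.3, 1))
    if (n_edges(rn) == 0) next
    regions <- sample(rep(c(1L, 2L), each = 8))
    expect_equal(ei_index(rn, regions), ei_brute(rn, regions))
    expect_gte(ei_index(rn, regions), -1)
    expect_lte(ei_index(rn, regions), 1)
  }
})

test_that("E-I index boundary and error cases behave as defined", {
  # all region-1 out-links internal, region 2 edgeless -> -1
  net <- trade_network(4L, rbind(c(1L, 2L), c(2L, 1L)))
  regions <- c(1L, 1L, 2L, 2L)
  expect_equal(ei_index(net, regions), -1)
  # sign flips when the within/cross pattern is mirrored
  cross <- trade_network(4L, rbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(ei_index(cross, regions), 1)
  expect_error(ei_index(make_absent(4), c(1L, 1L, 2L, 2L)), "no edges")
  # focal-out denominator option: same numerator, different normalisation
  mix <- trade_network(4L, rbind(c(1L, 3L), c(3L, 4L), c(4L, 3L)))
  expect_equal(ei_index(mix, regions), 1 / 3)
  expect_equal(ei_index(mix, regions, denominator = "focal_out"), 1)
})

test_that("pairs-across E-I is constant 0.5 across seeded batch draws", {
  set.seed(5)
  for (i in 1:100) {
    net <- make_pairs_across(16)
    expect_identical(ei_index(net, attr(net, "regions")), 0.5)
  }
})
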