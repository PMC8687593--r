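test_that("seasonal catchability closes exactly the configured stock-window", {
  scen <- scenario_config("seasonality")
  # closed stock, week inside the window
  expect_equal(seasonal_catchability(scen, "A", 1, 4), 0)
  expect_equal(seasonal_catchability(scen, "A", 1, 26), 0)
  # same species, other region: never closed
  expect_equal(seasonal_catchability(scen, "A", 2, 4), 1)
  # other species, closed region
  expect_equal(seasonal_catchability(scen, "B", 1, 4), 1)
  # open half of the year, and the pattern repeats across years
  expect_equal(seasonal_catchability(scen, "A", 1, 27), 1)
  expect_equal(seasonal_catchability(scen, "A", 1, 52 + 3), 0)
  expect_equal(seasonal_catchability(scen, "A", 1, 52 + 30), 1)
  # baseline never closes anything
  base <- scenario_config("baseline")
  expect_equal(seasonal_catchability(base, "A", 1, 1:104), rep(1, 104))
  # configurable phase
  off <- scenario_config("seasonality", closure_offset = 26)
  expect_equal(seasonal_catchability(off, "A", 1, 3), 1)
  expect_equal(seasonal_catchability(off, "A", 1, 30), 0)
})

test_that("catch equals effort x stock x catchabilities at the fixed point", {
  cfg <- sim_config(network = make_absent(16), years = 1, replicates = 1,
                    summary_years = 1, record_details = TRUE)
  run <- run_simulation(cfg, seed = 1)
  # every trader's weekly catch per species equals its market share
  expect_equal(max(abs(run$details$caught - 6.25)), 0, tolerance = 1e-9)
  # e = 0.0125, S = 500: catch = 6.25
  expect_equal(run$details$caught[1, 1, 1], 0.0125 * 500, tolerance = 1e-12)
})

test_that("baseline calibrated world is an exact fixed point of the schedule", {
  for (net in list(make_absent(16), make_pairs_across(16))) {
    cfg <- sim_config(network = net, years = 2, replicates = 1,
                      summary_years = 1)
    run <- run_simulation(cfg, seed = 42)
    expect_lt(max(run$scarcity), 1e-6)
    expect_lt(max(abs(run$exploitation)), 1e-6)
    expect_lt(max(run$waste), 1e-6)
    # all 16 traders identical at the symmetric fixed point
    expect_equal(max(run$trader_supply) - min(run$trader_supply), 0,
                 tolerance = 1e-9)
  }
})

test_that("one week of the two-trader micro-world matches the hand ledger", {
  # T1: dealer, region 1, buys from the seller T2 in region 2.
  # Seasonality closes species A in region 1. Calibration with one trader
  # per region: E = 0.2, market share = 50 per species and trader.
  cfg <- micro_config()
  w <- fishtradenet:::init_world(cfg, micro_network(), c(1L, 2L))
  set.seed(1)

  ## week 1: no request history; T1 loses its whole catch of A
  out <- fishtradenet:::step_week(w)
  w <- out$world
  expect_equal(out$rec$scarcity, c(50, 0))
  expect_equal(out$rec$biomass, c(550, 500, 500, 500))  # A1 grows unfished
  expect_equal(out$rec$trader_supply, c(50, 100), ignore_attr = TRUE)

  ## week 2, computed by hand:
  ##   T1 requests 50 of A; T2's demand-driven proposal tilts to A:
  ##   de = E*(100/500, 50/500)/0.3-norm = (2/15, 1/15), pe = (E/2, E/2),
  ##   e_T2 = (7/60, 1/12) -> catch A = 7/60*500 = 175/3, catch B = 125/3.
  ##   T2's sellable surplus of A = 175/3 - 50 = 25/3, all sold to T1.
  out <- fishtradenet:::step_week(w)
  rec <- out$rec
  expect_equal(out$world$effort[2, ], c(A = 7 / 60, B = 1 / 12),
               tolerance = 1e-9)
  expect_equal(out$world$effort[1, ], c(A = 0.1, B = 0.1), tolerance = 1e-9)
  expect_equal(rec$ledger$caught[2, ], c(175 / 3, 125 / 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rec$ledger$bought[1, 1], 25 / 3, tolerance = 1e-9)
  expect_equal(rec$ledger$sold_to_traders[2, 1], 25 / 3, tolerance = 1e-9)
  expect_equal(rec$scarcity, c(125 / 3, 25 / 3), tolerance = 1e-9)
  expect_equal(rec$waste, c(0, 0))
  expect_equal(rec$biomass, c(599.5, 500, 1475 / 3, 1525 / 3),
               tolerance = 1e-9)
  # ledger balance for both traders and species
  bal <- rec$ledger$caught + rec$ledger$bought - rec$ledger$sold_to_traders -
    rec$ledger$sold_to_market - rec$ledger$waste
  expect_equal(max(abs(bal)), 0, tolerance = 1e-9)
})

test_that("sellers ration concurrent requests pro-rata by requested amount", {
  # 8 traders, 4 per region; dealers T1, T2 (region 1) and T7, T8 (region 2).
  # T1 buys from sellers T3 and T4; T2 only from T3. Effort changes are
  # frozen (tiny cap), species A region 1 is closed, and stock A in region 2
  # is raised to 600 so each region-2 trader lands 15 against a share of
  # 12.5. T1's shortfall of 12.5 splits 6.25/6.25 over T3/T4; T2 requests
  # 12.5 from T3. T3's surplus 2.5 is rationed 2.5 * (6.25, 12.5)/18.75;
  # T4 serves T1's 6.25 up to its own surplus 2.5.
  net <- trade_network(8L, rbind(c(1L, 3L), c(1L, 4L), c(2L, 3L),
                                 c(7L, 5L), c(8L, 6L)))
  regions <- c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)
  cfg <- sim_config(network = net, scenario = "seasonality",
                    traders_per_region = 4L, years = 1L, replicates = 1L,
                    summary_years = 1L, max_change_fraction = 1e-12)
  w <- fishtradenet:::init_world(cfg, net, regions)
  w$S[1L, 2L] <- 600  # species A, region 2
  set.seed(7)
  rec <- fishtradenet:::step_week(w)$rec

  expect_equal(rec$ledger$bought[1, 1], 2.5 * 6.25 / 18.75 + 2.5,
               tolerance = 1e-9)
  expect_equal(rec$ledger$bought[2, 1], 2.5 * 12.5 / 18.75, tolerance = 1e-9)
  expect_equal(rec$ledger$sold_to_traders[3, 1], 2.5, tolerance = 1e-9)
  expect_equal(rec$ledger$sold_to_traders[4, 1], 2.5, tolerance = 1e-9)
  # transfers conserve fish: market A supply is the region-2 catch
  expect_equal(rec$supply[1], 4 * 15, tolerance = 1e-9)
  expect_equal(rec$scarcity[1], 100 - 60, tolerance = 1e-9)
})

test_that("requests are fully served when surplus is not binding", {
  # one dealer buying from two sellers whose surplus exceeds its requests
  net <- trade_network(8L, rbind(c(1L, 3L), c(1L, 4L)))
  regions <- c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L)
  cfg <- sim_config(network = net, scenario = "seasonality",
                    traders_per_region = 4L, years = 1L, replicates = 1L,
                    summary_years = 1L, max_change_fraction = 1e-12)
  w <- fishtradenet:::init_world(cfg, net, regions)
  w$S[1L, 2L] <- 999
  set.seed(7)
  rec <- fishtradenet:::step_week(w)$rec
  # T3/T4 land 0.025*999 = 24.975 each, surplus 12.475 >= the 6.25 requests
  expect_equal(rec$ledger$bought[1, 1], 6.25 + 6.25, tolerance = 1e-9)
  expect_equal(rec$ledger$sold_to_traders[3, 1], 6.25, tolerance = 1e-9)
  expect_equal(rec$ledger$sold_to_traders[4, 1], 6.25, tolerance = 1e-9)
})

test_that("total catch is scaled down when it would exceed the stock", {
  # r = 3 calibrates per-trader effort to E = 3, so the raw catch 1.5 * S
  # exceeds the standing stock and must be rationed to exactly S
  cfg <- micro_config(scenario = "baseline", r = 3)
  w <- fishtradenet:::init_world(cfg, micro_network(), c(1L, 2L))
  set.seed(1)
  rec <- fishtradenet:::step_week(w)$rec
  expect_equal(rec$ledger$caught[, 1], c(500, 500), tolerance = 1e-9)
  expect_true(all(rec$biomass >= 0))
  expect_equal(rec$biomass, rep(750, 4), tolerance = 1e-9)
})

test_that("same master seed reproduces a run bit-identically", {
  cfg <- sim_config(network = read_edge_list(fixture_network_path("more_dealers")),
                    scenario = "catch_variability", years = 2, replicates = 1,
                    summary_years = 1)
  r1 <- run_simulation(cfg, seed = 123)
  r2 <- run_simulation(cfg, seed = 123)
  expect_identical(r1$scarcity, r2$scarcity)
  expect_identical(r1$biomass, r2$biomass)
  expect_identical(r1$trader_supply, r2$trader_supply)
  expect_identical(r1$regions, r2$regions)
  r3 <- run_simulation(cfg, seed = 124)
  expect_false(identical(r1$trader_supply, r3$trader_supply))
})

test_that("region 2 is isolated from a region-1 closure without a network", {
  base <- sim_config(network = make_absent(16), scenario = "baseline",
                     years = 3, replicates = 1, summary_years = 1)
  seas <- sim_config(network = make_absent(16), scenario = "seasonality",
                     years = 3, replicates = 1, summary_years = 1)
  rb <- run_simulation(base, seed = 77)
  rs <- run_simulation(seas, seed = 77)
  expect_identical(rs$biomass[, c("A2", "B2")], rb$biomass[, c("A2", "B2")])
  # region 1 is affected (species A grows unfished during the closure)
  expect_false(identical(rs$biomass[, "A1"], rb$biomass[, "A1"]))
})

test_that("a connected network raises region-2 effort on the closed species", {
  cfg <- sim_config(network = make_pairs_across(16), scenario = "seasonality",
                    years = 3, replicates = 1, summary_years = 1,
                    record_details = TRUE)
  run <- run_simulation(cfg, seed = 5)
  r2 <- which(run$regions == 2L)
  wk <- 105:156
  closed <- ((wk - 1) %% 52) < 26
  effA2 <- rowSums(run$details$effort[wk, r2, 1])
  # above the calibrated 0.1 during the closure, relaxing when it ends
  expect_gt(mean(effA2[closed]), 0.105)
  expect_lt(mean(effA2[!closed]), mean(effA2[closed]))
})

test_that("run_batch derives independent reproducible child seeds", {
  cfg <- sim_config(network = make_pairs_across(16), scenario = "seasonality",
                    years = 1, replicates = 3, summary_years = 1)
  b1 <- run_batch(cfg, seed = 9)
  b2 <- run_batch(cfg, seed = 9)
  expect_identical(b1$run_table, b2$run_table)
  expect_equal(nrow(b1$run_table), 3L)
  expect_equal(length(unique(b1$child_seeds)), 3L)
  # pairs-across: E-I constant 0.5 in every replicate
  expect_identical(b1$run_table$ei, rep(0.5, 3))
})

test_that("invalid configurations are rejected before any stepping", {
  expect_error(sim_config(r = -0.1), "`r` must be positive")
  expect_error(sim_config(br = 2), "br")
  expect_error(sim_config(years = 0), "years")
  expect_error(sim_config(network = make_absent(4)), "2 \\* traders_per_region")
  expect_error(sim_config(summary_years = 30), "summary_years")
  # several problems reported together
  err <- tryCatch(sim_config(r = -1, br = 7), error = conditionMessage)
  expect_match(err, "`r` must be positive")
  expect_match(err, "br")
})
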