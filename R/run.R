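#' Run one simulation
#'
#' Executes `years * 52` weekly steps of the full nine-activity schedule:
#' market-demand refresh, fish requests and information transmission, combined
#' effort allocation, catchability draws, fishing and stock growth, two-phase
#' trading (requested trade, then random-order offers), and final-market sales
#' with waste. Traders are allocated randomly between regions (balanced in
#' numbers and trader types) unless the network carries a bundled assignment
#' (e.g. [make_pairs_across()]) or `regions` is supplied. All stochasticity —
#' network generation (for generator specs), region allocation, individual
#' catchability, and the random activation orders of the trading and market
#' phases — flows from the single `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this run.
#' @param regions Optional explicit region assignment (named or plain integer
#'   vector of 1/2 per trader).
#' @return An object of class `trade_run`: weekly series (`supply`,
#'   `scarcity`, `overabundance`, `waste` — weeks x markets A/B;
#'   `biomass` and `exploitation` — weeks x stocks A1, B1, A2, B2;
#'   `trader_supply` — weeks x traders), run metadata (`ei`, `regions`,
#'   `trader_types`, `out_degree`, `seed`), the terminal-window `summary`
#'   (see [summarize_run()]), and, when `config$record_details` is set,
#'   per-week effort and ledger arrays under `details`.
#' @export
run_simulation <- function(config, seed = 1L, regions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  net <- realize_network(config$network, config$traders_per_region)
  n <- n_traders(net)
  if (n != 2L * config$traders_per_region)
    stop("network size must equal 2 * traders_per_region", call. = FALSE)
  if (is.null(regions)) regions <- attr(net, "regions")
  if (is.null(regions)) regions <- assign_regions(net, config$traders_per_region)
  regions <- as.integer(regions)
  if (length(regions) != n || any(!regions %in% c(1L, 2L)) ||
      sum(regions == 1L) != config$traders_per_region)
    stop("invalid region assignment", call. = FALSE)
  ty <- trader_types(net)
  if (sum(ty[regions == 1L] == "dealer") != sum(ty[regions == 2L] == "dealer"))
    stop("region assignment must balance trader types", call. = FALSE)
  ei <- if (n_edges(net) > 0L) ei_index(net, regions) else NA_real_

  weeks <- config$years * 52L
  w <- init_world(config, net, regions)
  supply <- scarcity <- overab <- waste <- matrix(NA_real_, weeks, 2L,
                                                  dimnames = list(NULL, c("A", "B")))
  biomass <- matrix(NA_real_, weeks, 4L,
                    dimnames = list(NULL, c("A1", "B1", "A2", "B2")))
  tsupply <- matrix(NA_real_, weeks, n, dimnames = list(NULL, trader_names(net)))
  details <- NULL
  if (isTRUE(config$record_details)) {
    details <- list(
      effort = array(NA_real_, c(weeks, n, 2L)),
      caught = array(NA_real_, c(weeks, n, 2L)),
      bought = array(NA_real_, c(weeks, n, 2L)),
      sold_to_traders = array(NA_real_, c(weeks, n, 2L)),
      sold_to_market = array(NA_real_, c(weeks, n, 2L)),
      waste = array(NA_real_, c(weeks, n, 2L))
    )
  }
  for (t in seq_len(weeks)) {
    out <- step_week(w)
    w <- out$world
    rec <- out$rec
    supply[t, ] <- rec$supply
    scarcity[t, ] <- rec$scarcity
    overab[t, ] <- rec$overabundance
    waste[t, ] <- rec$waste
    biomass[t, ] <- rec$biomass
    tsupply[t, ] <- rec$trader_supply
    if (!is.null(details)) {
      details$effort[t, , ] <- rec$effort
      details$caught[t, , ] <- rec$ledger$caught
      details$bought[t, , ] <- rec$ledger$bought
      details$sold_to_traders[t, , ] <- rec$ledger$sold_to_traders
      details$sold_to_market[t, , ] <- rec$ledger$sold_to_market
      details$waste[t, , ] <- rec$ledger$waste
    }
  }
  run <- structure(
    list(
      supply = supply, scarcity = scarcity, overabundance = overab,
      waste = waste, biomass = biomass,
      exploitation = exploitation_index(biomass, K = config$K),
      trader_supply = tsupply,
      ei = ei, regions = stats::setNames(regions, trader_names(net)),
      trader_types = ty, out_degree = out_degree(net),
      market_demand = calibrate(config$r, config$K,
                                config$traders_per_region)$market_demand_per_species,
      seed = as.integer(seed), config = config, details = details
    ),
    class = "trade_run"
  )
  run$summary <- summarize_run(run)
  run
}

#' @export
print.trade_run <- function(x, ...) {
  weeks <- nrow(x$scarcity)
  cat(sprintf(
    "<trade_run> %d weeks, %d traders, scenario '%s', E-I = %s\n",
    weeks, ncol(x$trader_supply), x$config$scenario$kind,
    ifelse(is.na(x$ei), "NA (no edges)", format(round(x$ei, 4)))
  ))
  s <- x$summary$markets
  cat(sprintf("  median scarcity (last window): A = %.3f, B = %.3f\n",
              s$scarcity_median[1L], s$scarcity_median[2L]))
  cat(sprintf("  median exploitation: %s\n",
              paste(sprintf("%s %.1f%%", x$summary$stocks$stock,
                            x$summary$stocks$exploitation_median), collapse = ", ")))
  invisible(x)
}

#' Run a batch of replicate simulations
#'
#' Runs `config$replicates` independent simulations. The master seed
#' deterministically produces one child seed per replicate, so a batch is
#' reproducible bit-exactly and replicates are independent. Region assignments
#' (and generator-spec networks) are redrawn per replicate from each child
#' seed.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param keep_runs Keep the full `trade_run` objects (memory-heavy; default
#'   keeps only the per-run summaries).
#' @return An object of class `trade_batch`; see [aggregate_batch()] for the
#'   table layout.
#' @export
run_batch <- function(config, seed = 1L, keep_runs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  runs <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    runs[[i]] <- run_simulation(config, seed = child_seeds[i])
  }
  batch <- aggregate_batch(runs)
  batch$master_seed <- as.integer(seed)
  batch$child_seeds <- child_seeds
  if (keep_runs) batch$runs <- runs
  batch
}

#' @export
print.trade_batch <- function(x, ...) {
  cat(sprintf("<trade_batch> %d replicates, scenario '%s'\n",
              nrow(x$run_table), x$config$scenario$kind))
  cat(sprintf("  median of run-median scarcity: A = %.3f, B = %.3f\n",
              stats::median(x$run_table$scarcity_A),
              stats::median(x$run_table$scarcity_B)))
  invisible(x)
}
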