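#' Scenario configuration
#'
#' The exogenous catch-dynamics scenario a simulated world is exposed to:
#' * `"baseline"` — no perturbation; the calibrated world sits at the MSY
#'   fixed point.
#' * `"seasonality"` — seasonal species catchability `sc = 0` for one species
#'   in one region during `closed_weeks_per_year` of each 52-week year
#'   (default: species A, region 1, 26 weeks — 6 of 12 months); all other
#'   stocks keep `sc = 1`.
#' * `"catch_variability"` — each trader's weekly catch is multiplied by an
#'   individual catchability `ic` drawn from Normal(`ic_mean`, `ic_sd`)
#'   (defaults 1 and 0.2, i.e. 20% stochastic variability), clamped at 0.
#'
#' @param kind Scenario kind.
#' @param closed_species,closed_region Stock affected by the seasonal closure.
#' @param closed_weeks_per_year Length of the closure (weeks of 52).
#' @param closure_offset Week-of-year (0-based) at which the closure starts.
#' @param ic_mean,ic_sd Individual-catchability distribution; `ic_sd` defaults
#'   to 0.2 for `"catch_variability"` and 0 otherwise.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("baseline", "seasonality", "catch_variability"),
                            closed_species = "A", closed_region = 1L,
                            closed_weeks_per_year = 26L, closure_offset = 0L,
                            ic_mean = 1, ic_sd = NULL) {
  kind <- match.arg(kind)
  closed_species <- match.arg(as.character(closed_species), c("A", "B"))
  closed_region <- as.integer(closed_region)
  if (!closed_region %in% c(1L, 2L)) stop("`closed_region` must be 1 or 2", call. = FALSE)
  closed_weeks_per_year <- as.integer(closed_weeks_per_year)
  if (closed_weeks_per_year < 0L || closed_weeks_per_year > 52L)
    stop("`closed_weeks_per_year` must be in 0..52", call. = FALSE)
  if (is.null(ic_sd)) ic_sd <- if (kind == "catch_variability") 0.2 else 0
  if (ic_sd < 0) stop("`ic_sd` must be non-negative", call. = FALSE)
  structure(
    list(kind = kind, closed_species = closed_species,
         closed_region = closed_region,
         closed_weeks_per_year = closed_weeks_per_year,
         closure_offset = as.integer(closure_offset) %% 52L,
         ic_mean = ic_mean, ic_sd = ic_sd),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s", x$kind))
  if (x$kind == "seasonality")
    cat(sprintf(": species %s closed in region %d for %d weeks/year",
                x$closed_species, x$closed_region, x$closed_weeks_per_year))
  if (x$kind == "catch_variability")
    cat(sprintf(": ic ~ Normal(%g, %g) clamped at 0", x$ic_mean, x$ic_sd))
  cat("\n")
  invisible(x)
}

#' Seasonal species catchability
#'
#' The binary multiplier `sc` implementing closed seasons: 0 if and only if
#' the scenario is `"seasonality"`, the stock matches the closed
#' (species, region) pair, and the week falls inside the closure window of
#' its 52-week year; 1 otherwise.
#'
#' @param scenario A [scenario_config()].
#' @param species `"A"` or `"B"` (vectorised).
#' @param region 1 or 2 (vectorised).
#' @param week 1-based simulation week (vectorised).
#' @return 0/1 numeric vector.
#' @export
seasonal_catchability <- function(scenario, species, region, week) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (any(week < 1L)) stop("`week` must be >= 1", call. = FALSE)
  if (scenario$kind != "seasonality")
    return(rep(1, max(length(species), length(region), length(week))))
  woy <- (as.integer(week) - 1L) %% 52L  # 0-based week of year
  in_window <- ((woy - scenario$closure_offset) %% 52L) < scenario$closed_weeks_per_year
  closed <- in_window & species == scenario$closed_species &
    region == scenario$closed_region
  as.numeric(!closed)
}

#' Simulation configuration
#'
#' Bundles everything one experiment cell needs: the trade network (an object
#' or a generator specification regenerated per replicate), the scenario, the
#' ecological parameters, the decision parameters, and the execution plan.
#' Defaults reproduce the standard setup: 16 traders (8 per region), r = 0.2
#' per week, K = 1000, br = 0.5, 20-year runs of 52-week years, 300
#' replicates, outcomes summarised over the last 5 years.
#'
#' @param network A [trade_network()] (fixed across replicates) or a list
#'   `list(kind = , ...)` with `kind` one of `"absent"`, `"pairs_across"`,
#'   `"fully_connected"`, `"erdos_renyi"`, `"motif_biased"`, `"file"`;
#'   stochastic generators are redrawn for every replicate.
#' @param scenario A [scenario_config()] or a scenario kind string.
#' @param r,K Stock growth rate per week and carrying capacity.
#' @param traders_per_region Traders in each region (network size must be
#'   twice this).
#' @param br Balance rate of the combined decision algorithm.
#' @param max_change_fraction Weekly per-species effort-change cap (of `E`).
#' @param years Simulated years (52 weeks each).
#' @param replicates Number of independent runs in a batch.
#' @param summary_years Length of the terminal summary window in years.
#' @param requests `"current"` (default: activity-7 trade requests are
#'   recomputed from the current shortfall, demand minus fish on hand)
#'   or `"activity2"` (reuse the start-of-week information-transmission
#'   quantities).
#' @param de_base What the demand-driven decision sub-model allocates effort
#'   in proportion to. The default `"effort_to_demand"` uses the effort needed
#'   to land each species' total demand at last week's catch rate
#'   (`D_s / CPUE_s`): a trader aims its effort split at meeting demand, and a
#'   species that is not "biting" absorbs the whole demand-driven proposal. At
#'   the default balance rate 0.5 and equal demands this proposal exactly
#'   mirrors the CPUE-driven one, so an unperturbed region holds its effort
#'   split — only demand asymmetries (partner requests, unequal markets) move
#'   it. The alternatives allocate proportionally to gross demand
#'   (`"total_demand"`), to last week's unmet part of it
#'   (`"residual_demand"`), or to blends of the two
#'   (`"demand_plus_residual"`, `"demand_balance"`); all produce weaker or
#'   less stable effort responses and are retained for sensitivity analysis.
#' @param requests_base `"market_share"` (default) or `"total_demand"`: the
#'   demand concept whose shortfall a dealer requests from its partners. With
#'   the default, a dealer requests the part of its own final-market share its
#'   fishers (and last week's purchases) did not cover; partner requests still
#'   enter its total demand — and hence its effort allocation and what it will
#'   buy opportunistically — but are not themselves re-requested upstream.
#'   With `"total_demand"`, shortfalls of partner-demand are re-requested too;
#'   in reciprocal structures this lets two partners echo the same final-market
#'   demand back and forth, inflating demand without bound during a closure and
#'   propagating effort responses into the region the closure already affects.
#' @param record_details Record per-trader effort and full ledgers each week
#'   (needed for conservation audits; off by default).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(network = make_absent(16L),
                       scenario = scenario_config("baseline"),
                       r = 0.2, K = 1000, traders_per_region = 8L,
                       br = 0.5, max_change_fraction = 0.2,
                       years = 20L, replicates = 300L, summary_years = 5L,
                       requests = c("current", "activity2"),
                       de_base = c("effort_to_demand", "demand_plus_residual",
                                   "demand_balance", "residual_demand",
                                   "total_demand"),
                       requests_base = c("market_share", "total_demand"),
                       record_details = FALSE) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  requests <- match.arg(requests)
  de_base <- match.arg(de_base)
  requests_base <- match.arg(requests_base)
  years <- as.integer(years)
  replicates <- as.integer(replicates)
  summary_years <- as.integer(summary_years)
  traders_per_region <- as.integer(traders_per_region)
  problems <- character()
  if (!(inherits(network, "trade_network") ||
        (is.list(network) && !is.null(network$kind))))
    problems <- c(problems, "`network` must be a trade_network or a generator spec list")
  if (!is.numeric(r) || r <= 0) problems <- c(problems, "`r` must be positive")
  if (!is.numeric(K) || K <= 0) problems <- c(problems, "`K` must be positive")
  if (is.na(traders_per_region) || traders_per_region < 1L)
    problems <- c(problems, "`traders_per_region` must be >= 1")
  if (!is.numeric(br) || br < 0 || br > 1) problems <- c(problems, "`br` must be in [0, 1]")
  if (!is.numeric(max_change_fraction) || max_change_fraction <= 0)
    problems <- c(problems, "`max_change_fraction` must be positive")
  if (is.na(years) || years < 1L) problems <- c(problems, "`years` must be >= 1")
  if (is.na(replicates) || replicates < 1L) problems <- c(problems, "`replicates` must be >= 1")
  if (is.na(summary_years) || summary_years < 1L || summary_years > max(years, 1L))
    problems <- c(problems, "`summary_years` must be in 1..years")
  if (inherits(network, "trade_network") &&
      n_traders(network) != 2L * traders_per_region)
    problems <- c(problems, "network size must equal 2 * traders_per_region")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  structure(
    list(network = network, scenario = scenario, r = r, K = K,
         traders_per_region = traders_per_region, br = br,
         max_change_fraction = max_change_fraction, years = years,
         replicates = replicates, summary_years = summary_years,
         requests = requests, de_base = de_base,
         requests_base = requests_base,
         record_details = record_details),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  netdesc <- if (inherits(x$network, "trade_network")) {
    sprintf("%d traders, %d edges", n_traders(x$network), n_edges(x$network))
  } else {
    paste0("generator '", x$network$kind, "'")
  }
  cat(sprintf(
    "<sim_config> %s scenario, network [%s]\n  r = %g/wk, K = %g, %d traders/region, br = %g\n  %d years x 52 weeks, %d replicates, summary window %d years\n",
    x$scenario$kind, netdesc, x$r, x$K, x$traders_per_region, x$br,
    x$years, x$replicates, x$summary_years
  ))
  invisible(x)
}

# Materialise the network for one replicate (generator specs are redrawn from
# the current RNG stream; fixed objects pass through).
realize_network <- function(network, traders_per_region) {
  if (inherits(network, "trade_network")) return(network)
  spec <- network
  n <- if (!is.null(spec$n)) as.integer(spec$n) else 2L * traders_per_region
  switch(spec$kind,
    absent = make_absent(n),
    pairs_across = make_pairs_across(n),
    fully_connected = make_fully_connected(n),
    erdos_renyi = make_erdos_renyi(n, spec$n_edges,
                                   dealer_fraction = spec$dealer_fraction %||% 1),
    motif_biased = make_motif_biased(n, spec$n_edges,
                                     dealer_fraction = spec$dealer_fraction %||% 1,
                                     reciprocity_weight = spec$reciprocity_weight %||% 0,
                                     centralization_weight = spec$centralization_weight %||% 0),
    file = read_edge_list(spec$path),
    stop("unknown network kind: ", spec$kind, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: build the mutable world for one run. `regions` is a length-n
# integer vector. All traders start at the symmetric effort split E/2 with no
# history, which is the calibrated MSY fixed point.
init_world <- function(config, net, regions) {
  n <- n_traders(net)
  tpr <- config$traders_per_region
  cal <- calibrate(config$r, config$K, tpr)
  em <- edge_matrix(net)
  outdeg <- as.integer(out_degree(net))
  # edge indices grouped by responder (the trader being bought from)
  edges_to <- split(seq_len(nrow(em)), factor(em[, 2L], levels = seq_len(n)))
  buyers_of <- lapply(edges_to, function(ix) em[ix, 1L])
  dealer_ids <- which(outdeg > 0L)
  e0 <- matrix(cal$per_trader_total_effort / 2, n, 2L,
               dimnames = list(NULL, c("A", "B")))
  list(
    n = n, tpr = tpr, regions = as.integer(regions),
    E = cal$per_trader_total_effort,
    share = cal$per_trader_market_share,
    demand = cal$market_demand_per_species,
    r = config$r, K = config$K,
    br = config$br, cap = config$max_change_fraction,
    requests = config$requests,
    de_base = config$de_base,
    requests_base = config$requests_base,
    scenario = config$scenario,
    em = em, outdeg = outdeg, edges_to = edges_to, buyers_of = buyers_of,
    dealer_ids = dealer_ids,
    # stocks: rows = species (A, B), cols = regions (1, 2)
    S = matrix(config$K / 2, 2L, 2L, dimnames = list(c("A", "B"), NULL)),
    effort = e0,
    prev_demand = matrix(0, n, 2L),
    prev_catch = matrix(0, n, 2L),
    prev_bought = matrix(0, n, 2L),
    prev_effort = matrix(0, n, 2L),
    week = 0L
  )
}

# Internal: advance the world one week through the nine activities.
# Returns list(world, rec) where rec holds the week's outcome records.
step_week <- function(w) {
  n <- w$n
  eps <- 1e-12
  week <- w$week + 1L
  regions <- w$regions

  ## (1) market demand refresh: exogenous constant, per-trader share w$share

  ## (2) dealers predict shortfall and split requests over out-links
  base_prev <- if (w$requests_base == "market_share")
    matrix(w$share, n, 2L) else w$prev_demand
  unmet <- unmet_demand(base_prev, w$prev_catch, w$prev_bought)
  if (w$week == 0L) unmet[] <- 0  # no history yet
  per_partner <- split_requests(unmet, w$outdeg)

  ## (3) traders update incoming partner requests
  inc <- matrix(0, n, 2L)
  m <- nrow(w$em)
  if (m > 0L) {
    agg <- rowsum(per_partner[w$em[, 1L], , drop = FALSE], w$em[, 2L])
    inc[as.integer(rownames(agg)), ] <- agg
  }
  D <- total_demand(matrix(w$share, n, 2L), inc)

  ## (4) combined effort allocation
  de_demand <- switch(w$de_base,
    effort_to_demand = {
      # effort needed to land D at last week's catch rate; a species that is
      # not "biting" (CPUE ~ 0) needs unbounded effort and absorbs the whole
      # demand-driven proposal
      cpue <- ifelse(w$prev_effort > 0, w$prev_catch / w$prev_effort, 0)
      D / pmax(cpue, 1e-9)
    },
    total_demand = D,
    residual_demand = pmax(D - w$prev_catch - w$prev_bought, 0),
    demand_plus_residual = D + pmax(D - w$prev_catch - w$prev_bought, 0),
    demand_balance = pmax(2 * D - w$prev_catch - w$prev_bought, 0)
  )
  de <- demand_driven_effort(de_demand, w$E, w$effort)
  pe <- cpue_driven_effort(w$prev_catch, w$prev_effort, w$E, w$effort)
  e_new <- combine_efforts(de, pe, w$br, w$E, w$effort, w$cap)

  ## (5) catchability draws
  sc <- matrix(1, 2L, 2L)
  scen <- w$scenario
  if (scen$kind == "seasonality") {
    sp <- if (scen$closed_species == "A") 1L else 2L
    woy <- (week - 1L) %% 52L
    if (((woy - scen$closure_offset) %% 52L) < scen$closed_weeks_per_year)
      sc[sp, scen$closed_region] <- 0
  }
  ic <- if (scen$ic_sd > 0) pmax(0, stats::rnorm(n, scen$ic_mean, scen$ic_sd))
        else rep(1, n)

  ## (6) fishing and stock update
  S_trader <- cbind(w$S[1L, regions], w$S[2L, regions])
  sc_trader <- cbind(sc[1L, regions], sc[2L, regions])
  catch <- e_new * S_trader * ic * sc_trader
  tot <- rowsum(catch, regions)            # regions x species
  stock_tot <- t(w$S)[as.integer(rownames(tot)), , drop = FALSE]
  f <- ifelse(tot > stock_tot & tot > 0, stock_tot / tot, 1)
  if (any(f < 1)) {
    catch <- catch * cbind(f[regions, 1L], f[regions, 2L])
    tot <- rowsum(catch, regions)
  }
  S_new <- w$S
  for (reg in 1:2) for (sp in 1:2) {
    S <- w$S[sp, reg]
    C <- tot[reg, sp]
    S_new[sp, reg] <- min(max(S + w$r * S * (1 - S / w$K) - C, 0), w$K)
  }

  on_hand <- catch
  caught <- catch
  bought <- matrix(0, n, 2L)
  sold_t <- matrix(0, n, 2L)
  sold_m <- matrix(0, n, 2L)
  waste <- matrix(0, n, 2L)

  ## (7) requested trade: sellers first, then dealers in random order
  if (m > 0L) {
    base_now <- if (w$requests_base == "market_share")
      matrix(w$share, n, 2L) else D
    short <- if (w$requests == "current") pmax(base_now - on_hand, 0) else unmet
    req_pp <- split_requests(short, w$outdeg)
    req_edge <- req_pp[w$em[, 1L], , drop = FALSE]
    serve <- function(v) {
      ix <- w$edges_to[[v]]
      for (s in 1:2) {
        reqs <- req_edge[ix, s]
        tot_req <- sum(reqs)
        if (tot_req <= eps) next
        surplus <- on_hand[v, s] - w$share
        if (surplus <= eps) next
        fct <- min(1, surplus / tot_req)
        tr <- reqs * fct
        buyers <- w$em[ix, 1L]
        on_hand[v, s] <<- on_hand[v, s] - sum(tr)
        sold_t[v, s] <<- sold_t[v, s] + sum(tr)
        on_hand[buyers, s] <<- on_hand[buyers, s] + tr
        bought[buyers, s] <<- bought[buyers, s] + tr
        req_edge[ix, s] <<- reqs - tr
      }
    }
    seller_resp <- which(w$outdeg == 0L & lengths(w$edges_to) > 0L)
    for (v in seller_resp) serve(v)
    dealer_resp <- w$dealer_ids[lengths(w$edges_to[w$dealer_ids]) > 0L]
    if (length(dealer_resp) > 1L) dealer_resp <- sample(dealer_resp)
    for (v in dealer_resp) serve(v)
  }

  ## (8) offer trade: random-order offers along incoming edges until no
  ##     feasible transfer remains. A buyer's residual need is measured
  ##     against the fish it has acquired this week (caught + bought), so
  ##     passing fish on does not re-open demand and the phase terminates.
  if (m > 0L) {
    repeat {
      moved <- FALSE
      for (v in sample.int(n)) {
        bs <- w$buyers_of[[v]]
        if (!length(bs)) next
        for (s in 1:2) {
          surplus <- on_hand[v, s] - w$share
          if (surplus <= eps) next
          order_b <- if (length(bs) > 1L) sample(bs) else bs
          for (u in order_b) {
            need <- D[u, s] - caught[u, s] - bought[u, s]
            if (need <= eps) next
            tr <- min(surplus, need)
            on_hand[v, s] <- on_hand[v, s] - tr
            on_hand[u, s] <- on_hand[u, s] + tr
            sold_t[v, s] <- sold_t[v, s] + tr
            bought[u, s] <- bought[u, s] + tr
            surplus <- surplus - tr
            moved <- TRUE
            if (surplus <= eps) break
          }
        }
      }
      if (!moved) break
    }
  }

  ## (9) market sales in random trader order; leftover fish is wasted
  supply <- numeric(2L)
  for (s in 1:2) {
    ord <- sample.int(n)
    oh <- on_hand[ord, s]
    remaining <- pmax(0, w$demand - c(0, cumsum(oh))[seq_len(n)])
    sold <- pmin(oh, remaining)
    sold_m[ord, s] <- sold
    waste[ord, s] <- oh - sold
    supply[s] <- sum(sold)
  }

  rec <- list(
    supply = supply,
    scarcity = pmax(0, w$demand - supply),
    overabundance = pmax(0, supply - w$demand),
    waste = colSums(waste),
    biomass = c(S_new),                       # A1, B1, A2, B2
    trader_supply = rowSums(sold_t) + rowSums(sold_m),
    effort = e_new,
    ledger = list(caught = caught, bought = bought, sold_to_traders = sold_t,
                  sold_to_market = sold_m, waste = waste)
  )

  w$S <- S_new
  w$prev_demand <- D
  w$prev_catch <- caught
  w$prev_bought <- bought
  w$prev_effort <- e_new
  w$effort <- e_new
  w$week <- week
  list(world = w, rec = rec)
}
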