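#' Scarcity and overabundance series
#'
#' Weekly fish scarcity of a market is the positive part of
#' `market demand - market supply`; overabundance is the positive part of the
#' reverse difference (unsold perishable fish, cf. waste). For any market-week
#' at most one of the two is positive.
#'
#' @param run A `trade_run` from [run_simulation()], or a numeric supply
#'   matrix/vector when `demand` is given.
#' @param demand Market demand per species (scalar), needed only when `run` is
#'   numeric.
#' @return Matrix (weeks x markets) of scarcity values.
#' @export
scarcity_series <- function(run, demand = NULL) {
  if (inherits(run, "trade_run")) return(pmax(run$market_demand - run$supply, 0))
  if (is.null(demand)) stop("`demand` required for a numeric supply series", call. = FALSE)
  pmax(demand - run, 0)
}

#' @rdname scarcity_series
#' @export
overabundance_series <- function(run, demand = NULL) {
  if (inherits(run, "trade_run")) return(pmax(run$supply - run$market_demand, 0))
  if (is.null(demand)) stop("`demand` required for a numeric supply series", call. = FALSE)
  pmax(run - demand, 0)
}

# terminal summary window (row indices) for a run of `weeks` weeks
summary_window <- function(weeks, summary_years) {
  win <- summary_years * 52L
  if (win < 1L || win > weeks) stop("summary window is empty or exceeds the run", call. = FALSE)
  (weeks - win + 1L):weeks
}

#' Per-trader supply statistics over the summary window
#'
#' A trader's weekly individual supply is the fish it manages to sell — to
#' other traders plus to the final markets, both species combined, excluding
#' waste. Returns the mean and standard deviation (and coefficient of
#' variation) of that weekly series over the terminal summary window, joined
#' with the trader's type and out-degree.
#'
#' @param run A `trade_run`.
#' @param window Integer vector of week indices; defaults to the configured
#'   summary window (last `summary_years` years).
#' @return A data.frame with one row per trader: `trader`, `type`,
#'   `out_degree`, `region`, `mean_supply`, `sd_supply`, `cv_supply`.
#' @export
trader_supply_stats <- function(run, window = NULL) {
  stopifnot(inherits(run, "trade_run"))
  if (is.null(window))
    window <- summary_window(nrow(run$trader_supply), run$config$summary_years)
  if (length(window) < 1L) stop("empty summary window", call. = FALSE)
  ts <- run$trader_supply[window, , drop = FALSE]
  mu <- colMeans(ts)
  sdv <- apply(ts, 2L, stats::sd)
  data.frame(
    trader = colnames(ts),
    type = unname(run$trader_types),
    out_degree = unname(run$out_degree),
    region = unname(run$regions),
    mean_supply = unname(mu),
    sd_supply = unname(sdv),
    cv_supply = unname(ifelse(mu > 0, sdv / mu, NA_real_)),
    row.names = NULL
  )
}

#' Summarise one run over its terminal window
#'
#' All outcome variables are summarised as the median over the last
#' `summary_years` years of the run: per-market scarcity and overabundance,
#' and per-stock exploitation index; additionally the across-week standard
#' deviation of scarcity within the window, and the per-trader supply
#' statistics from [trader_supply_stats()].
#'
#' @param run A `trade_run`.
#' @param window Optional explicit week indices.
#' @return A list with data.frames `markets` (one row per market),
#'   `stocks` (one row per stock) and `traders` (one row per trader), plus
#'   `ei` and `seed`.
#' @export
summarize_run <- function(run, window = NULL) {
  stopifnot(inherits(run, "trade_run"))
  if (is.null(window))
    window <- summary_window(nrow(run$scarcity), run$config$summary_years)
  sc <- run$scarcity[window, , drop = FALSE]
  ov <- run$overabundance[window, , drop = FALSE]
  ex <- run$exploitation[window, , drop = FALSE]
  list(
    markets = data.frame(
      market = c("A", "B"),
      scarcity_median = apply(sc, 2L, stats::median),
      scarcity_sd = apply(sc, 2L, stats::sd),
      overabundance_median = apply(ov, 2L, stats::median),
      row.names = NULL
    ),
    stocks = data.frame(
      stock = colnames(run$exploitation),
      exploitation_median = apply(ex, 2L, stats::median),
      biomass_median = apply(run$biomass[window, , drop = FALSE], 2L, stats::median),
      row.names = NULL
    ),
    traders = trader_supply_stats(run, window),
    ei = run$ei,
    seed = run$seed
  )
}

#' Aggregate replicate runs into a batch summary
#'
#' Collects the per-run terminal-window summaries of a set of replicate runs
#' (all sharing one configuration) into two tidy tables: `run_table` with one
#' row per run (E-I index, median scarcity/overabundance per market, median
#' exploitation per stock) and `trader_table` with one row per (run, trader)
#' (type, out-degree, mean and SD of weekly supply). No replicate is dropped.
#'
#' @param runs List of `trade_run` objects with identical configurations.
#' @return An object of class `trade_batch`.
#' @export
aggregate_batch <- function(runs) {
  if (!length(runs) || !all(vapply(runs, inherits, TRUE, "trade_run")))
    stop("`runs` must be a non-empty list of trade_run objects", call. = FALSE)
  key <- function(cf) paste(cf$scenario$kind, cf$r, cf$K, cf$traders_per_region,
                            cf$br, cf$years, cf$summary_years)
  keys <- vapply(runs, function(r) key(r$config), "")
  if (length(unique(keys)) != 1L)
    stop("runs have mixed configurations and cannot be aggregated", call. = FALSE)
  run_table <- do.call(rbind, lapply(seq_along(runs), function(i) {
    s <- runs[[i]]$summary
    ex <- stats::setNames(s$stocks$exploitation_median,
                          paste0("exploit_", s$stocks$stock))
    cbind(
      data.frame(run = i, seed = s$seed, ei = s$ei,
                 scarcity_A = s$markets$scarcity_median[1L],
                 scarcity_B = s$markets$scarcity_median[2L],
                 scarcity_sd_A = s$markets$scarcity_sd[1L],
                 scarcity_sd_B = s$markets$scarcity_sd[2L],
                 overabundance_A = s$markets$overabundance_median[1L],
                 overabundance_B = s$markets$overabundance_median[2L]),
      as.data.frame(as.list(ex))
    )
  }))
  trader_table <- do.call(rbind, lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]$summary$traders
    cbind(data.frame(run = i), tr)
  }))
  structure(
    list(run_table = run_table, trader_table = trader_table,
         replicates = length(runs), config = runs[[1L]]$config),
    class = "trade_batch"
  )
}

#' Association between spatial connectivity and market scarcity
#'
#' Spearman rank correlation, per market, between each run's E-I index
#' (spatial connectivity of region-1 traders) and its terminal-window median
#' scarcity, across the replicates of a batch with randomized region
#' assignment.
#'
#' @param batch A `trade_batch` (or its `run_table`).
#' @param min_runs Minimum number of usable runs.
#' @return Named numeric vector: correlation for markets A and B.
#' @export
ei_scarcity_association <- function(batch, min_runs = 10L) {
  tab <- if (inherits(batch, "trade_batch")) batch$run_table else batch
  tab <- tab[is.finite(tab$ei), , drop = FALSE]
  if (nrow(tab) < min_runs)
    stop("need at least ", min_runs, " runs with a defined E-I index", call. = FALSE)
  if (stats::sd(tab$ei) == 0)
    stop("E-I index is constant across runs; the association is undefined", call. = FALSE)
  c(
    A = stats::cor(tab$ei, tab$scarcity_A, method = "spearman"),
    B = stats::cor(tab$ei, tab$scarcity_B, method = "spearman")
  )
}
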