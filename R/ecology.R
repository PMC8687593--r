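#' Create a fish stock
#'
#' A single-species, single-region fish stock following discrete-time logistic
#' (Gordon-Schaefer surplus-production) dynamics. The four stocks of a
#' simulated world (two species x two regions) are parameter-identical at
#' initialisation and start at the biomass that produces maximum sustainable
#' yield, `K/2`.
#'
#' @param species Species identifier, `"A"` or `"B"`.
#' @param region Region identifier, `1` or `2`.
#' @param biomass Current standing stock biomass. Defaults to `K/2`.
#' @param r Intrinsic growth rate per week. Must be positive.
#' @param K Carrying capacity in biomass units. Must be positive.
#'
#' @return An object of class `fish_stock`.
#' @examples
#' s <- fish_stock("A", 1, r = 0.2, K = 1000)
#' step_stock(s, total_catch = 50)  # MSY harvest holds biomass at K/2
#' @export
fish_stock <- function(species = c("A", "B"), region = c(1L, 2L),
                       biomass = NULL, r = 0.2, K = 1000) {
  species <- match.arg(as.character(species), c("A", "B"))
  region <- as.integer(region)[1L]
  if (!region %in% c(1L, 2L)) stop("`region` must be 1 or 2", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a positive number", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("`K` must be a positive number", call. = FALSE)
  if (is.null(biomass)) biomass <- K / 2
  if (!is.numeric(biomass) || length(biomass) != 1L || !is.finite(biomass) ||
      biomass < 0 || biomass > K)
    stop("`biomass` must lie in [0, K]", call. = FALSE)
  structure(
    list(species = species, region = region, biomass = biomass, r = r, K = K),
    class = "fish_stock"
  )
}

#' @export
print.fish_stock <- function(x, ...) {
  cat(sprintf(
    "<fish_stock> species %s, region %d: S = %.3f (r = %g/wk, K = %g, S/K = %.1f%%)\n",
    x$species, x$region, x$biomass, x$r, x$K, 100 * x$biomass / x$K
  ))
  invisible(x)
}

#' Advance a fish stock by one week
#'
#' Applies the discrete logistic update
#' `S' = S + r S (1 - S/K) - C`, where `C` is the total harvest extracted by
#' all traders this week, and clamps the result to `[0, K]`.
#'
#' @param stock A [fish_stock()].
#' @param total_catch Total harvest `C` removed this week. Must be >= 0.
#' @return The updated `fish_stock` (only `biomass` changes).
#' @examples
#' s <- fish_stock("A", 1, biomass = 400, r = 0.3, K = 1000)
#' step_stock(s, 50)$biomass  # 400 + 0.3*400*0.6 - 50 = 422
#' @export
step_stock <- function(stock, total_catch) {
  stopifnot(inherits(stock, "fish_stock"))
  if (!is.numeric(total_catch) || length(total_catch) != 1L ||
      !is.finite(total_catch) || total_catch < 0)
    stop("`total_catch` must be a non-negative number", call. = FALSE)
  S <- stock$biomass
  S_new <- S + stock$r * S * (1 - S / stock$K) - total_catch
  stock$biomass <- min(max(S_new, 0), stock$K)
  stock
}

#' Stock exploitation index
#'
#' Percentage deviation of the standing stock from the biomass that produces
#' maximum sustainable yield (`S_MSY = K/2`):
#' `(S / S_MSY - 1) * 100`. Values below zero indicate overexploitation
#' relative to the MSY stock; values above zero, under-exploitation. The index
#' is bounded in `[-100, 100]`.
#'
#' @param stock A [fish_stock()], or a numeric biomass when `K` is given.
#' @param K Carrying capacity, needed only when `stock` is numeric.
#' @return The exploitation index in percent.
#' @examples
#' exploitation_index(fish_stock("A", 1, biomass = 250, r = 0.2, K = 1000)) # -50
#' @export
exploitation_index <- function(stock, K = NULL) {
  if (inherits(stock, "fish_stock")) {
    S <- stock$biomass
    K <- stock$K
  } else {
    S <- stock
    if (is.null(K)) stop("`K` required when `stock` is numeric", call. = FALSE)
  }
  if (any(K <= 0)) stop("carrying capacity must be positive", call. = FALSE)
  (S / (K / 2) - 1) * 100
}

#' Calibrate demand and effort to maximum sustainable yield
#'
#' Derives the exogenous market demand and the per-trader fishing effort such
#' that, with every trader splitting effort evenly between the two species,
#' each of the four stocks is harvested at exactly its maximum sustainable
#' yield `MSY = rK/4` and all market demand is met with neither scarcity nor
#' waste. Because weekly catch is `effort x biomass`, the per-stock equilibrium
#' total effort is `r/2` (so that `(r/2)(K/2) = rK/4`), shared equally among
#' the region's traders.
#'
#' @param r Stock growth rate per week.
#' @param K Carrying capacity.
#' @param traders_per_region Number of traders in each of the two regions.
#' @param species_count Number of species; the model is defined for 2.
#' @return A list of class `msy_calibration` with elements
#'   `msy_per_stock` (`rK/4`), `per_stock_effort` (`r/2`),
#'   `per_trader_total_effort` (the constant total effort `E` each trader
#'   shares between species), `market_demand_per_species` (`2 * MSY`; two
#'   stocks supply each market, one per region) and `per_trader_market_share`
#'   (demand divided by the total trader count).
#' @examples
#' calibrate(r = 0.2, K = 1000, traders_per_region = 8)
#' @export
calibrate <- function(r = 0.2, K = 1000, traders_per_region = 8L,
                      species_count = 2L) {
  if (!is.numeric(r) || r <= 0 || !is.numeric(K) || K <= 0)
    stop("`r` and `K` must be positive", call. = FALSE)
  traders_per_region <- as.integer(traders_per_region)
  if (is.na(traders_per_region) || traders_per_region < 1L)
    stop("`traders_per_region` must be a positive integer", call. = FALSE)
  if (as.integer(species_count) != 2L)
    stop("the model is defined for exactly 2 species", call. = FALSE)
  msy <- r * K / 4
  per_stock_effort <- r / 2
  E <- per_stock_effort * species_count / (traders_per_region * species_count) *
    species_count  # = r/(2 * traders_per_region) * species_count
  n_traders <- 2L * traders_per_region
  demand <- 2 * msy
  structure(
    list(
      msy_per_stock = msy,
      per_stock_effort = per_stock_effort,
      per_trader_total_effort = E,
      market_demand_per_species = demand,
      per_trader_market_share = demand / n_traders
    ),
    class = "msy_calibration"
  )
}

#' @export
print.msy_calibration <- function(x, ...) {
  cat("<msy_calibration>\n")
  cat(sprintf("  MSY per stock:             %g / week\n", x$msy_per_stock))
  cat(sprintf("  per-stock total effort:    %g\n", x$per_stock_effort))
  cat(sprintf("  per-trader total effort E: %g\n", x$per_trader_total_effort))
  cat(sprintf("  market demand per species: %g / week\n", x$market_demand_per_species))
  cat(sprintf("  per-trader market share:   %g / week\n", x$per_trader_market_share))
  invisible(x)
}
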