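#' Trader demand bookkeeping
#'
#' `total_demand()` is a trader's demand for one species this week: its
#' constant share of the final-market demand plus the fish its trading
#' partners have requested from it. `unmet_demand()` is the previous week's
#' shortfall: the positive part of last week's total demand minus last week's
#' own catch (traders request from partners only what their own fishers could
#' not land). All arguments are vectorised over traders and species.
#'
#' @param market_share Per-trader slice of the final-market demand.
#' @param incoming_requests Sum of partner requests addressed to the trader
#'   this week.
#' @return Numeric of the same shape as the inputs.
#' @export
total_demand <- function(market_share, incoming_requests) {
  if (any(market_share < 0) || any(incoming_requests < 0))
    stop("demand quantities must be non-negative", call. = FALSE)
  market_share + incoming_requests
}

#' @rdname total_demand
#' @param prev_demand Previous week's total demand.
#' @param prev_catch Previous week's own catch. At week 1 (no history) all
#'   history arguments are zero, so the shortfall is zero by convention.
#' @param prev_bought Fish bought from partners in the previous week
#'   (default 0). Demand met by buying does not re-trigger a request: without
#'   this damping, reciprocal partners echo each other's market demand back
#'   and forth indefinitely and fishing effort never relaxes when a closed
#'   season ends.
#' @export
unmet_demand <- function(prev_demand, prev_catch, prev_bought = 0) {
  pmax(prev_demand - prev_catch - prev_bought, 0)
}

#' Split a shortfall equally over trading partners
#'
#' A dealer requests its unmet demand in equal parts from all traders it buys
#' from (its out-links); all relationships are equally committed. Sellers have
#' no out-links and request nothing.
#'
#' @param unmet The trader's shortfall for one species.
#' @param out_degree Number of the trader's out-links.
#' @return The per-partner request (`unmet / out_degree`, or 0 for a seller).
#'   The requests over all partners sum to `unmet`.
#' @export
split_requests <- function(unmet, out_degree) {
  if (is.matrix(unmet)) {
    res <- unmet / out_degree  # out_degree recycles down the trader dimension
    res[out_degree == 0L, ] <- 0
    return(res)
  }
  ifelse(out_degree > 0, unmet / out_degree, 0)
}

#' Demand-driven optimal effort split
#'
#' The demand-driven decision sub-model: a trader's objective is to meet the
#' need for fish of the market and its trading partners, neither over- nor
#' under-supplying either species, so it proposes splitting its constant total
#' effort `E` in proportion to the two species' total demand. When both
#' demands are zero the current split is kept.
#'
#' @param demand `n x 2` matrix of total demand per trader (columns: species
#'   A, B).
#' @param total_effort Per-trader constant total effort `E` (scalar or length
#'   `n`).
#' @param current_effort `n x 2` matrix of the current effort split (the
#'   fallback).
#' @return `n x 2` matrix `de` with rows summing to `E`.
#' @export
demand_driven_effort <- function(demand, total_effort, current_effort) {
  demand <- rbind(demand)
  current_effort <- rbind(current_effort)
  tot <- demand[, 1L] + demand[, 2L]
  share <- ifelse(tot > 0, demand[, 1L] / tot,
                  current_effort[, 1L] / (current_effort[, 1L] + current_effort[, 2L]))
  cbind(A = total_effort * share, B = total_effort * (1 - share))
}

#' CPUE-driven optimal effort split
#'
#' The catch-per-unit-effort decision sub-model: a trader's (and its fishers')
#' objective is to maximise CPUE, so it proposes splitting `E` in proportion
#' to the realised CPUE of each species in the previous week
#' (`last_catch / last_effort`, taken as 0 where no effort was applied).
#' Fishers do not target species that are not "biting": a species with zero
#' CPUE receives no proposed effort while the other has positive CPUE. When
#' both CPUEs are zero (e.g. week 1) the current split is kept.
#'
#' @param last_catch,last_effort `n x 2` matrices of the previous week's own
#'   catch and applied effort.
#' @inheritParams demand_driven_effort
#' @return `n x 2` matrix `pe` with rows summing to `E`.
#' @export
cpue_driven_effort <- function(last_catch, last_effort, total_effort,
                               current_effort) {
  last_catch <- rbind(last_catch)
  last_effort <- rbind(last_effort)
  current_effort <- rbind(current_effort)
  cpue <- ifelse(last_effort > 0, last_catch / last_effort, 0)
  tot <- cpue[, 1L] + cpue[, 2L]
  share <- ifelse(tot > 0, cpue[, 1L] / tot,
                  current_effort[, 1L] / (current_effort[, 1L] + current_effort[, 2L]))
  cbind(A = total_effort * share, B = total_effort * (1 - share))
}

#' Combined demand/CPUE effort-allocation algorithm
#'
#' Balances the two decision sub-models with the balance rate `br` in `[0,1]`:
#' per species, the new effort moves from the demand-driven proposal `de`
#' toward the CPUE-driven proposal `pe` by the magnitude
#' `mag = br * |de - pe|` (equivalently `e = (1 - br) de + br pe`;
#' `br = 0` is purely demand-driven, `br = 1` purely CPUE-driven, and the
#' default 0.5 weighs both equally). The result is then normalised so the two
#' species' efforts sum exactly to the trader's constant total effort `E`, and
#' finally the weekly change of each species' effort is capped at
#' `max_change_fraction * E` (default 20%), with the complementary species
#' absorbing the clamp so the sum stays `E`.
#'
#' @param de,pe `n x 2` matrices from [demand_driven_effort()] and
#'   [cpue_driven_effort()].
#' @param br Balance rate in `[0, 1]`.
#' @param total_effort Constant per-trader total effort `E` (scalar or length
#'   `n`).
#' @param previous_effort `n x 2` matrix of last week's applied effort.
#' @param max_change_fraction Weekly per-species change cap as a fraction of
#'   `E`; use `Inf` to disable.
#' @return `n x 2` non-negative matrix with rows summing to `E`.
#' @export
combine_efforts <- function(de, pe, br, total_effort, previous_effort,
                            max_change_fraction = 0.2) {
  if (!is.numeric(br) || length(br) != 1L || is.na(br) || br < 0 || br > 1)
    stop("`br` must be a single number in [0, 1]", call. = FALSE)
  if (any(total_effort <= 0)) stop("`total_effort` must be positive", call. = FALSE)
  de <- rbind(de)
  pe <- rbind(pe)
  previous_effort <- rbind(previous_effort)
  e <- (1 - br) * de + br * pe
  tot <- e[, 1L] + e[, 2L]
  # degenerate all-zero proposal: fall back to the previous split
  zero <- tot <= 0
  if (any(zero)) {
    e[zero, ] <- previous_effort[zero, , drop = FALSE]
    tot[zero] <- e[zero, 1L] + e[zero, 2L]
  }
  e <- e * (total_effort / tot)
  if (is.finite(max_change_fraction)) {
    cap <- max_change_fraction * total_effort
    # rows sum to E both before and after, so dA = -dB; clamp symmetrically
    dA <- e[, 1L] - previous_effort[, 1L]
    m <- pmin(abs(dA), cap)
    eA <- previous_effort[, 1L] + sign(dA) * m
    e <- cbind(A = eA, B = total_effort - eA)
  }
  colnames(e) <- c("A", "B")
  e
}
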