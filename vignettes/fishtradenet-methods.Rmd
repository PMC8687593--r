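---
title: "The fishtradenet model: ecology, trading schedule and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fishtradenet model: ecology, trading schedule and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishtradenet)
```

## The system being modelled

Small-scale fisheries commonly feed two kinds of final demand through
networks of traders who hold stable, socially embedded relationships with
each other and with fishers. `fishtradenet` simulates such a system in a
deliberately stylized form: two fishing regions, each with its own stocks of
two non-substitutable finfish species (A and B), sixteen traders split
equally between the regions, and two final markets, one per species. Traders
come in two types distinguished by a single capability: *dealers* both buy
from and sell to other traders (out-degree ≥ 1 in the directed trade
network, where an edge `u -> v` reads "u requests from / buys from v"),
while *sellers* only sell what their own fishers land. The package's
question is how the structure of the trade network — the proportion of
dealers, the overall connectivity, and in particular the connectivity
*between* regions — shapes fish provision at the markets, the exploitation
of the stocks, and the supply of individual traders when catches fluctuate.

## Ecology and calibration

Each of the four stocks follows a discrete-time Gordon-Schaefer
surplus-production (logistic) update with weekly step,

$$S_{t+1} = S_t + r S_t (1 - S_t/K) - C_t,$$

where $C_t$ is the total harvest taken that week, and biomass is clamped to
$[0, K]$. All four stocks share $r$ and $K$ and start at $K/2$, the biomass
that produces maximum sustainable yield $\mathrm{MSY} = rK/4$. Weekly catch
is `effort x stock x ic x sc`, with `ic` a per-trader catchability
multiplier and `sc` a binary seasonal closure switch. Defaults are $r = 0.2$
per week and $K = 1000$ biomass units — an archetypical fast-growing finfish
stock; any positive values are accepted and all calibration quantities are
derived, not hard-coded.

`calibrate()` fixes the demand side so that the unperturbed system is an
*exact* fixed point: aggregate market demand per species equals $2 \cdot
\mathrm{MSY}$ (two stocks serve each market, one per region), each trader
holds an equal share of it, and each trader's constant total effort $E$ is
set so that the symmetric split $e_A = e_B = E/2$ harvests every stock at
exactly MSY. With 8 traders per region this gives $E = r/8$, a market demand
of $rK/2$ per species, and a per-trader market share of $rK/32$. The
exploitation index reported everywhere is $(S/S_{\mathrm{MSY}} - 1) \times
100$ with $S_{\mathrm{MSY}} = K/2$: negative values mean overexploitation.

## The weekly schedule

Each week executes nine activities in a fixed order:

1. **Market demand refresh** — exogenous and constant.
2. **Requests** — each dealer computes last week's shortfall and requests it
   in equal parts from all traders it buys from.
3. **Demand update** — every trader's total demand is its market share plus
   the requests now addressed to it.
4. **Effort allocation** — the combined decision algorithm (below) moves
   each trader's species split, capped at a 20%-of-$E$ change per week.
5. **Catchability draws** — `ic ~ Normal(1, 0.2)` clamped at zero in the
   catch-variability scenario (1 otherwise); `sc = 0` for species A in
   region 1 during the first 26 weeks of each 52-week year in the
   seasonality scenario (1 otherwise; the phase is configurable).
6. **Fishing** — catches realized; if the requested total exceeds a standing
   stock, all catches from that stock are scaled proportionally; stocks
   updated.
7. **Requested trade** — sellers first, then dealers in uniformly random
   order, serve the requests addressed to them from their *sellable
   surplus* (fish on hand beyond their own market share), pro-rata by
   request size when the surplus is insufficient.
8. **Offer trade** — traders in random order offer remaining surplus to the
   partners who buy from them (visited in random order); a buyer accepts up
   to its remaining unmet demand; the phase repeats until no feasible
   transfer remains.
9. **Market sales** — traders sell on-hand fish into their markets in random
   order until the aggregate demand is filled; everything left is waste
   (fish is perishable; there is no storage).

Every trader keeps a weekly ledger (caught, bought, sold to traders, sold to
market, waste) that balances exactly, and weekly mass balance holds: total
catch equals market supply plus waste.

## The combined decision algorithm

Traders balance two objectives when splitting their constant effort $E$
between the species: meeting demand, and fishing where the fish are. Two
sub-models each propose a full split, and the balance rate $br \in [0,1]$
mixes them per species as $e_s = de_s - \mathrm{sign}(de_s - pe_s)\, br\,
|de_s - pe_s|$ — algebraically $(1-br)\,de_s + br\,pe_s$ — followed by
renormalisation to $E$ and the 20% weekly change cap, with the other species
absorbing the clamp so the sum stays exactly $E$. At $br = 0$ the split is
purely demand-driven, at $br = 1$ purely CPUE-driven; the default 0.5
weights both equally. A sweep over $br$ is available through
`sim_config(br = ...)` for sensitivity analysis.

* The **CPUE-driven sub-model** (`cpue_driven_effort()`) splits $E$ in
  proportion to last week's realized catch-per-unit-effort of each species.
  A species that is not "biting" (CPUE 0) is not targeted at all; with no
  history, the current split is kept.
* The **demand-driven sub-model** (`demand_driven_effort()`) splits $E$ in
  proportion to a demand measure. The engine's default measure is the
  *effort needed to meet each species' demand at last week's catch rate*,
  $D_s/\mathrm{CPUE}_s$ — the most direct reading of "the effort that meets
  the demand". A proportional-to-demand measure, a residual-demand measure,
  and two blends are available via `sim_config(de_base = ...)`.

The effort-to-demand default has a property that anchors the whole design:
since realized CPUE is proportional to stock biomass, at $br = 0.5$ and
*equal* demands the two proposals cancel exactly and a trader holds its
split. Effort therefore moves only when demands are asymmetric — which is
precisely what partner requests create. A region that experiences no
closure and receives no requests behaves identically with and without a
network, so the spillover measured in the experiments is attributable to
the request mechanism alone. The alternative measures lack this property:
proportional-to-demand reacts too weakly to be distinguishable from
baseline noise, and residual-only is a bang-bang controller that overshoots
through the change cap and settles into multi-year limit cycles. Both
remain available as options and are useful for exploring how sensitive the
headline patterns are to the decision rule.

## Requests, damping and the composition question

Two further compositional choices were genuinely open and materially affect
the dynamics:

* **Shortfalls are damped by purchases.** A trader's next-week request is
  its demand minus what it *obtained* (own catch plus fish bought), not
  minus own catch alone. Without the purchase term, two reciprocal partners
  echo the same unit of final-market demand back and forth indefinitely:
  requested fish is delivered, yet re-requested forever, and demand grows
  without bound during a closure.
* **Requests are composed from the trader's own market-share shortfall**
  (`requests_base = "market_share"`). Partner requests still enter a
  trader's total demand — driving its effort allocation and its
  opportunistic buying — but are not themselves re-requested upstream. With
  the alternative (`"total_demand"`), boomerang requests inflate the closed
  region's demand and its effort allocation becomes strongly
  network-dependent, which contradicts the observed behaviour of the system
  this model emulates (the closed region's exploitation dynamics are driven
  by the closure, not by the network).

Activity-7 trade requests are recomputed from the current shortfall (demand
minus fish on hand after fishing); `requests = "activity2"` reuses the
start-of-week information instead.

## Scenarios and experiments

Three scenarios: `baseline` (nothing perturbed — the exact fixed point),
`seasonality` (species A uncatchable in region 1 for half of each year) and
`catch_variability` (20% multiplicative noise on every trader's weekly
catch). Five network structures are shipped as plain-text edge lists and
generators: no network (all sellers), reciprocal cross-region dealer pairs,
a fully connected network, and two *synthetic* empirically informed
structures with equal edge counts but contrasting dealer fractions (6/16
vs 12/16), generated once by the motif-biased generator (reciprocity and
buying-centralization biases) with documented seeds. They emulate the
described properties of real reference networks — one isolated trader,
mixed types, identical density — but are constructed stand-ins, not
empirical data.

Each run draws a uniformly random balanced allocation of traders to regions
(equal counts and equal type proportions; dealer counts must be even). The
pairs-across structure is the exception: it is *defined* relative to the
regions, so the generator bundles its own assignment and every run has a
direction-adapted E-I index of exactly 0.5. The E-I index of region 1 is
`(external - internal out-links of region-1 traders) / total links`; the
denominator follows the printed formula (all links), with the
focal-out-links alternative exposed as an option.

Batches derive one child seed per replicate from a master seed; a batch is
reproducible bit-exactly, and all randomness — network generation (for
generator specifications), region allocation, `ic` draws, and the random
activation orders of the trading and market phases — flows from the run
seed.

## Problem sizes, tolerances and degenerate inputs

The full experiment design (300 replicates of 20 years per cell) runs in
tens of minutes on one core; the package's test suite and acceptance script
use reduced batches chosen as the smallest that make the directional
patterns decisive at a 0.01 sign-test level: 50 replicates of 10 years for
the spillover comparisons, 100 replicates for the connectivity association,
50 for the dealer/seller contrast, and 20 randomized 5-year stress runs for
the conservation audit. Ledger balance and mass conservation are checked to
1e-9; the baseline fixed point to 1e-6 over 1040 weeks (floating-point
drift accumulates below 1e-10); effort conservation to 1e-12. Degenerate
inputs are handled explicitly: zero demands or zero CPUEs fall back to the
current split, a zero-edge network has an undefined E-I index (an error,
not 0), requested totals never exceed stocks or surpluses, and `ic` draws
are clamped at zero rather than resampled (documented, cheap, and
bias-free at sd = 0.2 to within 2e-7 of the mean).

## What the generators emulate — and what they do not

The synthetic structures and scenarios reproduce the *mechanisms* a real
regional trade system exhibits — seasonal closures, catch noise, reciprocal
and centralized trading relationships, mixed trader types — under a
deliberately symmetric ecology (identical stocks, constant aggregate
demand, no prices, no storage, no re-wiring of relationships). Passing
tests therefore demonstrate internal consistency and the direction of
network-mediated effects under those assumptions; they do not validate
magnitudes for any particular fishery, and none of the shipped edge lists
is an empirical network. Price formation, storage and freezing, dynamic
link creation, vertical value-chain actors, and ecological connectivity
between regions are out of scope by design.

## Known limitations

* The decision sub-models are reconstructions chosen for their behaviour,
  isolated behind `demand_driven_effort()` / `cpue_driven_effort()` and the
  `de_base` / `requests_base` options so alternatives can be swapped in.
* With all-dealer symmetric structures the seasonality scenario is
  effectively deterministic given the region assignment, so replicate
  distributions collapse; stochastic spread there comes only from the
  catch-variability scenario.
* Trader-level supply counts fish sold by each trader, so a fish passing
  through two dealers contributes to both traders' individual supply
  (correct for an individual-level metric; not a system throughput).
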