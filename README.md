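# fishtradenet

An agent-based, weekly-step simulator of **regional fish trade networks**
coupled to logistic fish stocks, for researchers studying how the social
structure of small-scale fishery trade — who buys from whom, in which
region — shapes fish provision to markets, stock exploitation, and the
livelihoods of individual traders under fluctuating catches.

## The model in brief

Two fishing regions each hold stocks of two non-substitutable species
(A and B) following discrete Gordon–Schaefer dynamics

S[t+1] = S[t] + r·S[t](1 − S[t]/K) − C[t],

with all four stocks starting at the MSY biomass K/2. Sixteen traders
(8 per region) are connected by a directed trade network in which an edge
u → v means "u requests fish from / buys from v"; traders with at least one
buying relationship are *dealers*, the rest are *sellers*. Market demand is
exogenous and calibrated so that each stock is harvested at exactly
MSY = rK/4 when every trader splits its constant effort E evenly — the
baseline is an exact fixed point with zero scarcity.

Each week traders request shortfalls from their partners, reallocate
fishing effort by balancing a demand-driven and a CPUE-driven heuristic
(balance rate `br`, default 0.5; at most a 20%-of-E change per week), fish,
trade in two phases (requested trade, then random-order offers), and sell
to the final markets; unsold fish is waste. Two disturbance scenarios are
built in: a half-year closure of species A in region 1 (*seasonality*) and
20% multiplicative catch noise (*catch variability*). Outcomes are market
scarcity `max(0, demand − supply)`, the stock exploitation index
`(S/(K/2) − 1)·100`, per-trader supply statistics, and a direction-adapted
E-I index measuring the cross-region connectivity of trade.

## Worked example

```r
library(fishtradenet)

calibrate(r = 0.2, K = 1000, traders_per_region = 8)
#> <msy_calibration>
#>   MSY per stock:             50 / week
#>   per-stock total effort:    0.1
#>   per-trader total effort E: 0.025
#>   market demand per species: 100 / week
#>   per-trader market share:   6.25 / week

net <- make_pairs_across(16)     # reciprocal cross-region dealer pairs
cfg <- sim_config(network = net, scenario = "seasonality",
                  years = 10, replicates = 5, summary_years = 5)
run_simulation(cfg, seed = 1)
#> <trade_run> 520 weeks, 16 traders, scenario 'seasonality', E-I = 0.5
#>   median scarcity (last window): A = 21.165, B = 0.775
#>   median exploitation: A1 43.7%, B1 -0.0%, A2 -7.9%, B2 7.6%
```

Reading the numbers: during the half-year closures market A runs short
(median scarcity 21.2 of a demand of 100 — without any trade network it
would be 25), because traders in region 1 request species A from their
region-2 partners, who shift effort toward it. That spillover overexploits
the seasonal species in region 2 (A2 at −7.9% relative to the MSY stock)
and under-exploits the other (B2 at +7.6%), and the displaced effort makes
market B slightly scarce (0.775) where the no-network run has essentially
none. Stock A1 is under-exploited (+43.7%) simply because it cannot be
fished half the year; region-1 outcomes are unaffected by the network.

Batches aggregate replicates into tidy tables:

```r
batch <- run_batch(cfg, seed = 1)
batch$run_table[1, c("ei", "scarcity_A", "scarcity_B", "exploit_A2")]
#>    ei scarcity_A scarcity_B exploit_A2
#> 1 0.5      21.16     0.7747     -7.892
```

Five network structures ship as plain-text edge lists
(`fixture_network_path()`): `absent`, `pairs_across`, `fully_connected`,
and two synthetic empirically informed structures, `empirical_sim`
(6 dealers / 10 sellers) and `more_dealers` (12 dealers), with equal edge
counts. Generators (`make_erdos_renyi()`, `make_motif_biased()`) and an
experiment-grid runner (`run_experiment_grid()`) cover the sensitivity
designs. A command-line driver with `run`, `grid` and `make-network`
subcommands is installed at `inst/cli/fishtradenet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fishtradenet.R", package = "fishtradenet"))')" \
    grid --networks absent,more_dealers --scenarios seasonality \
    --replicates 50 --years 10 --out results/grid
```

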