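---
title: "agrosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{agrosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrosim)
```

`agrosim` is a desk-scale simulator of the coupled global land-use and food
system: biophysically anchored crop yield responses, income-driven food
demand, per-country least-cost allocation of land and inputs on clustered
grid cells, and a non-equilibrium world commodity market, advanced together
in an annual loop.  Everything runs on a synthetic world, so the whole
pipeline is generated, executed and audited in seconds.  This vignette
documents the model equations, the tunable parameters and their defaults,
the numerical choices, and what the synthetic world does and does not
emulate.

## The synthetic world

`generate_world()` builds a miniature world on the 0.5-degree lattice (cell
centres at odd multiples of a quarter degree; a cell owns
`[lon, lon + res)`).  Countries are rectangular blocks of cells; each cell
carries land-cover fractions (one per crop, pasture, forest, other natural,
urban/barren) that close to one, a protection fraction bounded by the
natural fraction, runoff, an aridity index, and membership in a food
production unit (FPU) — a watershed-scale pool over which irrigation water
is shared.

Yield potentials are supplied as *anchors*: for every cell and crop, the
attainable yield at the six factorial input combinations of fertiliser
(0, 200 and 1,000 kgN/ha — the top rate deliberately beyond practice, an
upper bound on attainable yield) crossed with rain-fed versus fully
irrigated water supply.  The generator draws smooth random fields (Gaussian
kernel smoothing of white noise over cell coordinates, kernel length one
degree) for soil fertility, aridity and the anchor gains, which makes
neighbouring cells within a country positively correlated — a property the
clustering stage relies on and the tests verify with Moran's I.  Anchors
are monotone by construction: the 200-anchor adds a positive gain to the
zero-fertiliser yield, the 1,000-anchor adds a smaller positive gain (at
most 90% of the 200-gain, so responses always saturate), and irrigated
yields multiply rain-fed ones by `1 + 0.8 * aridity` — arid places respond
most to water.

Socio-economics are generated to match the demand model's assumptions:
per-capita consumption of each commodity group lies on a known log-log
income curve (see `demand_truth()`) plus a country offset and log-normal
noise, so demand fitting can be tested against the generating coefficients.
Populations are sized so that baseline food and feed demand occupies a
modest share of each country's land at mid-range intensity — the baseline
is feasible by construction, not by luck.  Baseline net imports are a
centred ±10% perturbation of consumption, so world trade balances in the
base year.

What the generator does **not** emulate: real geography or borders, actual
climate forcing or its interannual variability, crop physiology beyond the
anchor structure, real FPU delineations, and observed price levels.
Passing tests therefore demonstrate that the *mechanisms* are implemented
coherently — conservation, monotonicity, convergence, optimality on small
instances — not that the package reproduces any observed global statistic.

## Yield-response surfaces

`fit_yield_surface()` turns the six anchors into a continuous yield
function.  Within each water regime the fertiliser response is a saturating
exponential through the three anchors,

$$y(F) = y_0 + (y_\infty - y_0)\,(1 - e^{-k_F F}),$$

with $k_F$ solved from the anchor ratio
$(y_{200}-y_0)/(y_{1000}-y_0) = (1-e^{-200k})/(1-e^{-1000k})$ by
`uniroot` to $10^{-12}$; the ratio is monotone in $k$ from 0.2 (linear) to
1 (instant saturation), so the root is unique.  Flat anchors
($y_{1000} \le y_0$) give $k_F = 0$ and a constant curve; a noisy middle
anchor above the top one is clamped.  Irrigation blends the two regimes
with a concave weight $w(x) = (1-e^{-k_I x})/(1-e^{-k_I})$ of the
irrigation fraction $x$ (default $k_I = 2$), and management — the composite
of pesticides, machinery, liming, reseeding — multiplies yield by
$g(m) = g_0 + (1-g_0)(1-e^{-k_M m})/(1-e^{-k_M})$ with floor $g_0 = 0.5$
and shape $k_M = 2$; $g(1) = 1$ by construction, so full management attains
the anchors exactly.  All three dimensions have diminishing returns, which
the tests check as non-positive second differences on a
$10\times10\times10$ lattice.

Two further multipliers complete the surface: a calibration factor — the
population of `calibrate_factor()`, a weighted least-squares slope through
the origin of observed on simulated yields, the standard translation from
simulated potential to observed units — and exogenous technology change
$(1+r)^{t-2010}$ with a central rate of $r = 0.2\%$ per year, representing
yield gains (plant breeding) above what intensification can deliver.

The separable form (fertiliser curve per regime, concave blend, concave
management multiplier) was one of several possibilities; it was chosen
because it is the simplest family that is exponential in every input,
reproduces all six anchors exactly, and is monotone and concave everywhere.
Whether the response should be jointly rather than separably fitted is an
open modelling question; the anchor grid cannot distinguish the two.

## Demand

`fit_demand_model()` regresses log per-capita consumption on log per-capita
income per commodity group, weighting observations by population.  The
log-log form supports both behaviours seen in dietary data: income-elastic
groups (livestock products, oil crops) with $b > 0$ rising at a decreasing
absolute rate, and staples (pulses, starchy roots) with $b < 0$ declining
but bounded below by zero.  Country offsets $d_0$ — persistent cultural
differences from the global curve — are the base-year residuals.
`project_demand()` either holds offsets constant or, with dietary
convergence on, shrinks them as income grows:
$d(t) = d_0\,e^{-\kappa \max(0,\,\ln g_t - \ln g_0)}$, which contracts
$|d|$ monotonically and never flips its sign.  There is no price
elasticity of demand: consumption responds to income and population only.

Bioenergy is exogenous: first-generation demand (fuel from food crops)
ramps linearly from its 2010 baseline to twice that level by 2030 and is
constant thereafter; the global demand for dedicated second-generation
energy crops rises linearly from 34 Mt DM/yr in 2010 to 4,000 Mt DM/yr in
2100 and is not assigned to countries — production locations emerge from
the optimisation.  The linear interpolations are the simplest curves
consistent with the stated endpoints.

Within-group commodity proportions are fixed from the base year; cereal
demand can be met by any mix of the three cereal crops.

## Clustering and disaggregation

Optimising every cell is wasteful; `cluster_country()` groups similar,
potentially non-contiguous cells within a country by k-means on
standardised features (per-crop anchor yields at 200 kgN/ha for both water
regimes plus cover fractions; z-scored within country because yields and
fractions live on different scales).  `choose_k()` scales cluster count
with size and heterogeneity, $k = \lceil 0.5\sqrt{n}\,(1+\mathrm{cv})
\rceil$ clamped to $[1, n]$, with a perfectly homogeneous country
collapsing to one cluster.  Assignment is deterministic given the seed and
invariant to cell order (cells are canonically sorted first); k-means runs
with 25 restarts, which on test-sized instances recovers the global optimum
found by exhaustive partition search.

Cluster-level decisions return to cells by `disaggregate()`: expansion of
an agricultural class is spread over member cells in proportion to their
*available natural* area (forest plus other natural above the larger of
the protected fraction and the minimum-natural reserve), debited equally
from forest and other natural while both have headroom; contraction is
proportional to each cell's current area of the shrinking class and
returns land to other natural vegetation.  Cluster deltas are conserved to
$10^{-9}$ and no fraction leaves $[0,1]$.

## The country optimiser

For one country and year, `optimise_country()` chooses, for every cluster
and each of the eight land-use types (seven crops plus pasture), the four
decision variables — area, fertiliser rate, irrigation fraction and
management intensity — plus country-level livestock feed and trade, to
minimise

$$\text{production costs} + \text{conversion costs} +
  \text{import costs} - \text{export revenue}$$

subject to (i) commodity balance (production + imports − exports − feed ≥
food plus first-generation bioenergy demand), (ii) cluster water budgets,
(iii) protected areas, (iv) the minimum natural fraction (default 0.05 per
cell), (v) equal debit of forest and other natural land on expansion, and
(vi) optionally a national deforestation cap of 1.1% of forest area per
year.  Per-hectare cost is a base cost (about a third of an intensive
system's cost — the minimum to produce at all) plus input costs, each an
intensity times a cost rate: fertiliser at \$/kgN, irrigation water at an
aridity-scaled \$/km³ on the volume *withdrawn* (the crop requirement
divided by the irrigation efficiency $\eta = 0.5$, within the global
0.294–0.855 range), and management at \$/ha.  Pasture carries a low base
cost representing extensive grazing.  Monogastric livestock eat feed only
(`fcr` 4 t per t product); ruminants (`fcr` 7) mix pasture and feed, which
is where pasture-to-cropland substitution enters.  Import prices are
inflated by tariff, transport and loss rates; export revenue is the world
price.

The solver is a deterministic merit-order allocation rather than a
black-box nonlinear search, chosen so that every allocation step is
auditable and the solution is reproducible without multi-start heuristics.
For each cluster, land-use type and land tier — existing cropland, existing
pasture, expansion into convertible natural land, each with its one-off
conversion cost — the intensity lattice is reduced to its efficient
frontier (the lower convex hull of per-hectare cost against yield) and
decomposed into a *base* increment that occupies land at the
cost-per-tonne-minimising intensity and *upgrade* increments that intensify
already-occupied land along the hull at increasing marginal cost per tonne
without consuming land.  A single sweep in ascending marginal cost then
resolves the central intensification-versus-expansion margin exactly for a
single limiting resource (the increments form a convex supply curve), and
the tests hold it to within 2% of an exhaustive coarse-lattice oracle on
two-cluster instances — in practice it matches or beats the oracle because
its lattice is no coarser.  Import options compete in the same sweep at
the inflated world price; production for export continues past demand
while marginal cost stays below the world price (2% margin).

Two behaviours are disciplined beyond the plain sweep.  First, cross-class
conversion (crops using pasture land at the cheap cropland–pasture
conversion cost, or vice versa) is capped at the other class's *surplus*,
computed by a preliminary own-class-only pass: converting land the other
class still needs would force that class to rebuild on natural land at a
higher combined cost, and the myopic sweep would otherwise churn land
between classes indefinitely across spin-up iterations.  Second, per-year
exports are capped (0.3 of domestic demand per food commodity; for energy
crops 0.6 of world demand) as a proxy for trade frictions and handling
capacity, so a single year's optimisation cannot flood the world market.

Water enters as a per-cluster budget from `build_water_budget()`: FPU
runoff minus non-agricultural consumption minus an environmental reserve,
allocated equally across the FPU's cells.  Within a cluster, irrigation is
implicitly distributed in proportion to cell availability, so FPU-level
limits are respected after disaggregation.

## The world market

`settle_market()` aggregates country trade, adds second-generation energy
demand, and computes per-commodity oversupply
$O = \text{exports} - \text{imports} - \text{demand}_{2g}$.  Stocks absorb
the imbalance, floored at zero with any shortfall logged as unmet demand,
and prices adjust exponentially against *relative* oversupply:

$$p' = p\,\exp\!\left(-\lambda\, O / \max(\text{imports} +
\text{demand}_{2g},\,\varepsilon)\right),$$

so price strictly falls when exports exceed imports and rises in the
opposite case — supply and demand need not clear in any year.  The
denominator floor $\varepsilon$ defaults to a tenth of the gross traded
volume, keeping the relative imbalance bounded when one side of the market
is empty, and the log step is clamped to $\pm 1$ (at most an $e$-fold move
per year) as a numerical safeguard that preserves the direction of the
feedback.

The adjustment rate $\lambda$ must lie inside the contraction region of
the settlement map: the composition of price update and supply response is
a fixed-point iteration, and for a response slope $s = |dO/dp|$ it
contracts roughly when $\lambda\,s\,p < 2\,\text{denominator}$.  A
three-country world with capped exports has a steep response (each
country's trade switches over a narrow price range), so the default is
$\lambda = 0.05$; the market property tests iterate a linear response and
verify the contraction directly.  Initial prices are exogenous in
principle, but by default (`prices_from_baseline`) they are re-anchored
after spin-up to the baseline solution's own marginal production costs —
the synthetic analogue of initialising from observed prices that are
consistent with observed costs — because arbitrary initial prices send the
market through years of avoidable import/export transients.  Initial
stocks are a stocks-to-use ratio (default 0.2) times baseline use.

## Spin-up and the annual loop

`spin_up()` initialises the land-use state: with demand and net imports
fixed at their base-year values (net imports as equalities), the country
optimisation is iterated on its own output — each round's land allocation
becomes the next round's existing land, so conversion costs progressively
anchor the solution — until the maximum relative change of any cluster
area or intensity value falls below 0.4% (default), or an iteration cap
(40) is reached, in which case the state is returned with a warning and a
flag.  The change metric is $|x' - x| / \max(|x'|, |x|, f)$ with per-
variable floors ($f$ = 10 ha for areas, 0.5 kgN/ha, 0.005 for the unit-
interval intensities) so that hectare-scale slivers in multi-Mha countries
cannot dominate convergence.  Intensity levels are not an input to the
initialisation — they emerge from the optimisation.

`run_timestep()` advances one year in a fixed order: (1) yield anchors are
the trailing mean of the annual anchor series over the averaging window
(default 5 years; the identity for constant anchors), (2) demand is
projected, (3) every country is optimised independently against the last
settled prices (countries in sorted order, which — because they interact
only through those fixed prices — makes results order-independent by
construction), (4) the market settles once, (5) cluster deltas are
disaggregated to cells and cluster aggregates rebuilt.  There is no
within-year price fixed-point: one settlement per year is the
non-equilibrium design.  Global exogenous trajectories (second-generation
bioenergy, initial stocks) are scaled by the ratio of the synthetic
world's land area to the real ~13,000 Mha, so the printed global values
remain meaningful at miniature scale.

`run_scenario()` wraps generation, initialisation, spin-up and the annual
loop, records global, country and market series plus decadal cell maps,
and replays bit-identically under the same seed (every internal seed is
derived deterministically from the master seed).  `run_ensemble()` samples
the ten declared cost parameters uniformly within ±`half_width` (default
50%) of their central values at Halton low-discrepancy points — a
deterministic quasi-random design, reproducible by construction — and
summarises per-year median and standard deviation of global cropland,
pasture, nitrogen and irrigation water.  `half_width` above 1 is rejected:
the sampled parameters are non-negative quantities.

## Problem sizes and what the tests show

The shipped configuration uses 3 countries × 20 half-degree cells and 7
crops — large enough for heterogeneous clusters, FPU pooling and
multi-commodity trade, small enough that the full suite (including
spin-up, a 7-year scenario, a 16-year constant-drivers run and small
ensembles) completes in about a minute.  The oracle comparisons run on 1–2
cluster instances where exhaustive lattice search is feasible.  A
constant-drivers scenario (anchors, socio-economics and bioenergy all held
at base-year values) drifts by well under 1% per decade after spin-up,
which is the package's stability audit: the coupled system holds a
steady state when nothing pushes it.

Known limitations: no bilateral trade (a single world market with one
price per commodity), no price elasticity of demand, no cropping calendars
or multi-cropping, no soil degradation, no climate-feedback coupling, and
livestock trade decisions use a binary import-or-produce comparison at
estimated feed cost rather than a joint optimisation.  These mirror the
scope of the modelling framework the package implements at desk scale.
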