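---
title: "Model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`baltfate` is a desk-scale box model of the fate of a neutral organic
chemical in a brackish, seasonally ice-covered sea under combined
*multistressor* pressure: chemical emissions, nutrient loads (eutrophication)
and climate. It is built for paired scenario experiments — run the same
weather twice, change one stressor, and read the contrast — rather than for
calibrated hindcasts of any real sea. This vignette documents the model
equations, the default parameterization and why it looks the way it does,
the numerical choices, and what the test suite does and does not establish.

## Model structure

The domain is a chain of basins, each with two fixed-volume layers (surface
and deep) plus an active sediment layer, draining through a designated open
boundary toward the outside sea. Three coupled process blocks advance on a
daily time step:

1. **hydro** — water and salt balances, surface heat exchange, sea ice;
2. **biogeo** — nutrient–phytoplankton–detritus (NPD) dynamics with
   dissolved and particulate organic carbon (DOC/POC);
3. **contaminant** — a dynamic mass balance of the chemical across water
   layers, phases and sediment.

The daily operator order is fixed: water/salt → heat/ice → biogeochemistry →
contaminant advection → air–water exchange → transformation →
settling/sediment exchange. A fixed order makes runs bit-reproducible; the
splitting error is O(dt) and acceptable at dt = 1 day because every process
rate in the default configuration is well below 1/day.

### Water and salt

Volumes are constant (rigid lid). Each basin's surface outflow equals its
river discharge, plus net precipitation minus evaporation over its area,
plus upstream surface inflows, plus the deep inflow entrained upward — so
water volume is conserved exactly at every step. Deep, salty inflows enter
each basin's deep layer at a configured rate, salinity and tracer
concentration (a parameterized stand-in for gravity-current inflows), and
are balanced by upward entrainment. A small diffusive exchange velocity
`vMix` (0.05 m/day) connects the layers for all tracers. Evaporation is a
fixed fraction (0.8) of precipitation rather than a latent-heat computation:
the contaminant model needs the water balance, not the heat balance.

### Heat and ice

Surface temperature relaxes toward air temperature with time constant
`tauSurf` = 14 days, using the exact exponential integrator, so a
constant-air run reproduces `T(t) = Ta + (T0 − Ta) e^(−t/τ)` to machine
precision. The deep layer relaxes toward the surface with `tauDeep` = 120
days. Below the salinity-dependent freezing point (`T_f = −0.054 S` °C, the
standard linearization) the water is pinned at `T_f` and freezing-degree-days
(FDD) accumulate; ice fraction is `min(1, FDD/fddFull)` with `fddFull` =
100 °C·day. Warming consumes the degree-day sum (melting) before the water
warms. The FDD sum saturates at `fddMemory × fddFull` with `fddMemory` = 1:
without a cap, a long Baltic winter banks hundreds of degree-days and ice
would survive into June; with the cap, ice cover starts responding as soon
as spring warming begins, placing melt-out in May and the winter
concentration peak in late winter/early spring, which is the regime the
model is meant to emulate. `iceEnabled = FALSE` zeroes the ice *fraction*
while leaving the thermal dynamics untouched — the clean way to isolate the
gas-exchange-blocking mechanism in paired runs.

### Nutrients, plankton and organic carbon

A single phytoplankton group grows at
`µmax · Q10^((T−20)/10) · I/(I+K_I) · min(N/(N+K_N), P/(P+K_P))`,
consuming DIN and DIP in Redfield mass proportion (C:N:P = 41:7.2:1).
Mortality routes carbon to detritus and, for the exudation fraction (0.2),
to a semi-labile DOC pool (first-order decay 0.002/day); the exudate's N and
P are remineralized immediately so DOC stays a carbon-only pool and the
elemental budgets close exactly. Detritus mineralizes back to nutrients at a
temperature-dependent rate and sinks (1.5 m/day) through the deep layer into
the sediment, whose organic carbon mineralizes (returning nutrients to the
deep layer) and buries. POC is *defined* as phytoplankton + detritus carbon
and never stored separately. Defaults (`µmax` = 1.2/day, mortality 0.08/day,
mineralization 0.03/day at 20 °C, Q10 = 2, K_N = 10 mg N/m³, K_P = 3 mg
P/m³, K_I = 25 W/m²) are literature-typical magnitudes with no claim of
matching any calibrated ecosystem model. There is no zooplankton, oxygen,
silica, nitrogen fixation, carbonate chemistry or self-shading: the
contaminant model needs organic-carbon pools that respond to loads and
temperature, not full marine ecology.

Growth is hard-capped at the nutrients actually present in a layer on a
given day, which keeps every pool non-negative under the explicit daily
step; the cap never binds at default rates but protects extreme
configurations. Consequently stiff configurations (e.g. a chemostat with
dilution approaching the growth rate) are only faithful to continuous-time
theory when all rates are well below 1/day — the chemostat oracle test is
parameterized accordingly.

### Contaminant

The chemical partitions among truly dissolved, DOC-bound and POC-bound
phases: `f_diss = 1/(1 + K_DOC·[DOC] + K_OC·[POC])` with sorbents in kg C/L;
the fractions sum to one exactly. Partition coefficients are
temperature-corrected by van't Hoff, `K(T) = K25 · exp((ΔU/R)(1/T −
1/298.15))`; with the D5 defaults ΔU_AW = −30 kJ/mol this makes the chemical
less volatile in cold water, and degradation rates follow Arrhenius,
`k(T) = k25 · exp((Ea/R)(1/298.15 − 1/T))`.

Air–water exchange uses the two-film model: water-side
`k_w = max(0.17·10⁻⁶ · u², 10⁻⁷)` m/s and air-side
`k_a = 10⁻³ (0.3 + 0.2 u)` m/s combine into
`k_OL = (1/k_w + 1/(k_a K_AW))⁻¹`, and the flux
`k_OL (C_air/K_AW − C_diss)(1 − ice)` is blocked linearly by ice fraction
(no gas transfer through leads beyond that linearity). Hydrolysis acts on
the truly dissolved fraction only — particle-sorbed mass is persistent —
while biodegradation acts on dissolved + DOC-bound mass in water and on the
sediment pool. First-order losses use exact `1 − e^(−k·dt)` factors so
closed-form decay checks hold to machine precision. POC-bound mass settles
with the detritus sinking velocity; the sediment exchanges with bottom water
by resuspension (10⁻⁴/day), permanent burial (5·10⁻⁵/day) and porewater
diffusion (10⁻² m/day) against a sorption equilibrium set by the sediment's
organic-carbon content, which the biogeo block supplies. All water flows
carry total (all-phase) concentration; the open boundary removes mass
permanently.

Everything in the contaminant block is linear in contaminant mass once
physics and biogeochemistry are fixed, so scaling all contaminant inputs by
α scales every concentration by α to machine precision. That linearity is
what makes the headline scenario result clean: a 90 % cut of the dominant
input pathway produces a 90 % concentration cut.

### D5 default chemical card

The default card emulates decamethylcyclopentasiloxane (D5): log K_OW = 8.1,
log K_AW = 3.1, log K_OC = 5.2 (direct, not derived from K_OW), K_DOC =
0.1·K_OC, hydrolysis half-life 65 days at 25 °C with Ea = 90 kJ/mol,
negligible biodegradation in water, sediment degradation half-life 1200
days, ΔU_AW = −30 kJ/mol, ΔU_OW = −20 kJ/mol — the EU risk-assessment
property profile at box-model fidelity. With these numbers volatilization
dominates the surface-water losses, the dissolved fraction is ~0.9, and the
chemical potential in water vastly exceeds that in air, so the sea outgasses
year-round wherever it is ice-free.

## Synthetic forcing and scenarios

The weather generator produces, per basin and variable, a sinusoidal
seasonal cycle plus one Gaussian annual anomaly per year (no interannual
autocorrelation): the simplest stationary "random weather". Non-negative
variables are truncated at zero. The same seed gives a bit-identical series,
and scenario comparisons share one realization so contrasts are purely
scenario-driven. The Baltic-like defaults place a cold, fresh, seasonally
ice-covered basin in the north (air temperature mean 2 °C, amplitude 11 °C),
a large temperate central basin carrying most of the river loads, a small
southern strait and a salty boundary basin; river discharge peaks in spring,
wind in winter, radiation at the solstice. Nutrient and contaminant loads
are constant baselines; the default contaminant loading is strongly
river-dominated (river loads 5–30 kg/day against an atmospheric
concentration of 0.5 ng/m³, whose absorbed flux is orders of magnitude
smaller because K_AW is large).

Scenario transforms:

* **Climate (a1b)** — wind ×1.07 and precipitation ×1.20 pointwise. The "on
  average 60 % higher air temperature" is implemented, by default, as a
  uniform per-basin offset of `0.6 × period-mean temperature`, so the
  period-mean °C ratio equals 1.60 exactly *and* winters warm. A literal
  pointwise ×1.60 would make sub-zero winter days colder and *increase* ice
  — the opposite of a warming scenario — so that reading is kept only as an
  explicit option (`a1bTempMode = "multiplicative"`), along with an optional
  linear ramp of the factors across the period (off by default so "on
  average" holds exactly).
* **Nutrients** — CL holds river DIN/DIP loads constant; IL ramps them
  linearly to 1.5× by 2100; BSAP ramps them to 0.6× by 2021 and holds
  constant after. The ramp shapes and endpoints are configurable; the IL
  magnitude is a design choice (no quantitative definition being available)
  and the BSAP endpoint reflects a load-reduction plan reaching its target
  around 2021.
* **Emissions** — `red_river` and `red_air` multiply the river contaminant
  load, respectively the atmospheric concentration, by
  `1 − reductionFraction` (default 0.9) from January 1 of `reductionYear`
  (default 2006). The atmosphere is prescribed as a concentration, not an
  emission flux: the scenario wording ("reduction of concentrations in the
  atmosphere") only makes sense for a prescribed concentration, and the
  model has no atmospheric transport.

Emission and nutrient transforms touch disjoint fields and therefore
commute.

## Numerical choices

* 365-day calendar, no leap days: seasonal indexing stays trivial and
  climatological fidelity is not a goal.
* Explicit Euler for transport and settling (all CFL-like ratios ≤ 0.2/day
  in the default geometry), exact exponential integrators for relaxation and
  first-order decay. Discrete fixed points of the transport scheme coincide
  with the continuous steady states, which is why the closed-form oracles
  (dilution L/Q, sediment D/(b+k), chemostat, relaxation) are meaningful
  verification targets.
* Budgets for water, salt, N, P and contaminant are accumulated from the
  same per-step flux numbers that update the state, so closure is exact to
  rounding (~10⁻¹⁵ relative); the engine aborts with a budget dump if
  closure exceeds `budgetTolerance` (10⁻³ by default). A deliberate-leak
  hook (`debugLeak`) exists solely to prove the abort fires.
* Ties in the winter-peak month are broken toward the earliest month;
  "winter" for reporting is December–April.
* An all-zero concentration year yields an NA peak amplitude, not an error.

## Design decisions that were genuinely open

* **Per-connection deep-inflow concentrations.** Deep inflows carry
  configured tracer concentrations. A single boundary concentration would
  feed the nutrient-poor northern basin with nutrient-rich southern water
  and erase its oligotrophy, so each connection may override the boundary
  default; the northern default inflow is nutrient-poor (DIN 30, DIP 4
  mg/m³).
* **Directed routing.** Surface transport follows a directed chain to the
  boundary. Bidirectional exchange between neighbour basins is not
  representable; the symmetric two-basin thought experiment is covered
  instead by the no-flow invariance and conservation tests.
* **DOC is carbon-only.** Tracking N and P through DOC would demand a
  stoichiometry for exudates that nothing downstream uses; immediate
  remineralization of exudate N/P keeps budgets exact with one fewer pool.
* **Sediment concentration tracks sediment organic carbon**: porewater
  concentration is `C_sed / (f_OC K_OC)`, so eutrophication-driven OC
  changes feed back on sediment–water exchange.
* **Radiative heating of water is off by default** (`radHeating = 0`):
  water temperature tracks air temperature alone, which keeps the climate
  signal interpretable through a single forcing variable; radiation still
  drives phytoplankton light limitation (attenuated by 0.25, and by 90 %
  under full ice).

## Problem sizes used in the tests

The test suite runs the default four-basin geometry for 41 years
(1990–2030) for the paired emission experiments, a single century run
(2001–2100) for budget closure and quasi-steady flux direction, 30-year
paired runs for the climate contrast, 10–12-year runs for the ice-peak and
load-response checks, and small single-box configurations for the
closed-form oracles. These sizes put every statistic well past its spin-up
transients (surface residence times are months; the sediment, the slowest
pool, equilibrates in a few years) while keeping the full suite to a few
minutes.

## What passing tests show — and what they do not

The generator emulates seasonal cycles, interannual noise, river-dominated
contaminant loading and Baltic-like contrasts between an oligotrophic
ice-covered north and a eutrophic temperate centre. It does *not* emulate
weather autocorrelation, storms, inflow events, spatial structure within
basins, seasonal thermocline migration, or realistic load time series. A
green suite therefore demonstrates internal correctness (conservation,
linearity, closed forms, determinism) and the *directional* multistressor
mechanisms: ice blocking creates winter concentration peaks; warming removes
ice and lowers long-run dissolved concentrations in ice-covered basins;
river-load cuts propagate ~1:1 into water concentrations while
air-concentration cuts do nothing when the sea already outgasses; detritus
rises monotonically with nutrient loads. Quantitative magnitudes beyond the
river-cut arithmetic (e.g. how much a warming climate lowers concentrations,
or detritus ratios between nutrient scenarios) depend on a calibrated
ecosystem and are deliberately out of scope.

## Known limitations

Single phytoplankton group and no higher trophic levels; no oxygen, silica
or carbonate system; prescribed rather than simulated atmospheric
concentrations; no catchment (river loads are forcing); directed surface
routing only; neutral chemicals only (no ionization, no metals); no
bioaccumulation. The model is a mechanism demonstrator and scenario-logic
testbed, not a decision-grade Baltic simulator.
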