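---
title: "From measured fluxes to per-MJ biodiesel emissions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From measured fluxes to per-MJ biodiesel emissions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmghg)
```

`palmghg` chains five stages: annual ecosystem greenhouse-gas budgets from
flux measurements, a soil-carbon decay model, rotation-cycle scenario
trajectories, a per-MJ life-cycle assembly, and Monte Carlo uncertainty. This
vignette explains the model in each stage, the assumptions and tunable
parameters, and the design choices made where the design was genuinely open.

## Sign conventions and constants

All fluxes are positive when directed from the ecosystem into the atmosphere.
CO₂-equivalent arithmetic uses fixed constants (`gwp_constants()`): the
carbon-to-CO₂ mass factor 3.664 (kept as the conventional printed value, not
44/12 recomputed), 100-year GWPs of 25 (CH₄) and 298 (N₂O), and the molecular
ratios 16/12 (CH₄-C → CH₄) and 44/28 (N₂O-N → N₂O). All annualizations use a
365-day, 8760-hour year; leap days are out of scope.

## Annual budgets from half-hourly NEE

A `flux_series` is a strictly increasing, uniform half-hourly record in
µmol CO₂ m⁻² s⁻¹ (or, for pre-aggregated data, gC m⁻² per half-hour).
`gapfill_diurnal()` replaces each gap by the mean of measured values at the
same time of day within ±7 days, widening the window in 7-day steps until at
least three donors exist. This is deliberately simpler than
covariate-driven gap-filling: it preserves the diurnal cycle, which carries
most of the half-hourly variance, and it is exact for any series whose
expected flux depends only on time of day. It will bias results when gaps
coincide with weather regimes that shift the diurnal shape — which is why
series with ≥ 50% gaps are refused rather than filled. Gap-filled records
are flagged (`qc = 2`) and measured values are never altered.

`integrate_annual_nee()` requires whole calendar months, converts
µmol CO₂ m⁻² s⁻¹ to carbon mass per slot (× 1800 s × 12.011 µg µmol⁻¹), sums
to a period total and extrapolates linearly to 12 months (total × 12/m). The
8-month young-plantation record is the motivating case for the
extrapolation; it assumes the unmeasured months behave like the measured
ones, an assumption the synthetic-data tests quantify but field seasonality
can violate.

Chamber campaigns are annualized by `trapezoid_annual()`: replicate means per
sampling date, trapezoidal integration over 8760 h, and constant extension of
the first and last campaign values to the year boundaries. The edge rule is a
choice (the alternative — cyclic wrap-around — changes constant-flux results
not at all and realistic ones by little); constant extension was chosen
because it is the unique rule under which a constant flux c mg m⁻² h⁻¹ gives
exactly c × 8.76 g m⁻² yr⁻¹ for *any* campaign schedule, a property the test
suite asserts.

The budget equations are exact arithmetic: NEP = NEE + C_yield (harvest
carbon export is an input, not derived from fruit composition);
NEE over peat or in a second rotation by soil-respiration substitution
(NEE − SR_measured + SR_substituted, which reduces to the identity when the
two respirations agree); GWP_net as the CO₂-equivalent sum; GHGI as GWP_net
divided by fresh-fruit-bunch yield converted to g m⁻² (× 100 per Mg ha⁻¹).

## Soil-carbon decay and second-rotation respiration

After forest conversion, relative soil carbon declines from 100% of the
forest reference toward an equilibrium fraction f. The published multi-site
decay dataset behind this behaviour is not refit here; instead
`calibrate_decay()` uses a two-parameter exponential form

r(t) = f + (1 − f)·exp(−k·t),

with f set by the observed equilibrium-to-reference stock ratio (default
0.60, back-computed from an equilibrium stock of 3.26 kgC m⁻² against a
5.43 kgC m⁻² forest reference) and k fixed by requiring that only 1% of the
initial excess remains at the equilibrium time (default 32.5 yr, the
midpoint of the 30–35-yr range over which plantation soil carbon levels
off). Both are exposed parameters, not hard-coded. The 1%-excess criterion is
a numerical convention making "equilibrium reached at t_eq" precise for a
curve that only reaches its asymptote at infinity.

Soil respiration is assumed to follow the same relative curve as soil carbon
stock. `respiration_from_anchor()` rescales a measured respiration (default
anchor: 133.9 mgC m⁻² h⁻¹ at plantation age 1) by r(t)/r(anchor age); the
resulting equilibrium respiration is ≈ 84.8 mgC m⁻² h⁻¹, equivalently
≈ 743 gC m⁻² yr⁻¹ by the 8.760 unit conversion. An independently reported
annual equilibrium respiration of 825 gC m⁻² yr⁻¹ exists in the literature
this builds on; it rests on annual-scale anchors that are not available
here, so this package derives the annual value strictly by unit conversion
from the hourly scale and documents the discrepancy rather than reproducing
the 825.

A second rotation starting at or after the first cycle's end sits on the
flat part of the curve: the largest excess over equilibrium respiration is
(1 − f)/f · exp(−26k) ≈ 1.7% in year one and decays monotonically.

## Scenario trajectories

Plantation-age trajectories are integer-year step functions. Management
inputs and NEE follow a plateau–ramp–plateau rule: constant at the
young-stand level through year 3, linear to the mature level at year 8,
constant to the end of the cycle. This piecewise-linear reading is the
anchor-truth of the module: with the young/mature anchors 88→196 (N),
73→220 (K), 38→50 (P) kg ha⁻¹ yr⁻¹ and 0→2250 ml ha⁻¹ yr⁻¹ (glyphosate) it
reproduces the four reported 25-yr life-cycle means (174.4, 190.6, 47.6,
1800) exactly, which the acceptance tests verify.

Yield ramps are anchored at zero in the year *before* first production
(year 3 for conventional varieties, so first fruit at year 4 is 1/5 of
maximum; year 2 for the earlier-yielding variety of scenario C), reaching
maximum at year 8 (6 for C). This convention mirrors the input-ramp rule. It
gives a 25-yr mean yield of 21.2 Mg ha⁻¹ yr⁻¹ against a reported simulated
mean of 21.925; the reported figure is not reproducible from any simple
linear ramp with a 26.5 Mg maximum, so `yield_trajectory()` also accepts an
explicit yield-by-age table should the exact values be available. The
mismatch is documented, not hidden, and yield-derived quantities in this
package use the ramp.

The four scenarios are business-as-usual (25-yr cycle), A (30 yr), B
(40 yr) and C (30 yr, earlier-yielding variety). Second-rotation variants
keep all management parameters, replace the NEE trajectory year-by-year via
the soil-respiration substitution (first-rotation SR evaluated at the
plantation's own age on the decay curve, second-rotation SR at
first-cycle-length + age), and carry no land-use-change charge.

## The LCA engine

The functional unit is 1 MJ of palm-oil biodiesel. `assemble_lca()` sums
per-hectare emissions over the whole rotation cycle, divides by the
cycle-total biodiesel energy, and applies energy allocation between
biodiesel and glycerol (energy shares of 37.5 and 16 MJ kg⁻¹ on a 95/5 mass
split of crude palm oil; the biodiesel factor is ≈ 0.978). Economic
allocation is available as a sensitivity through `allocation_factor()`.

The components are: the ecosystem sink (cumulative NEE plus soil CH₄ as
CO₂-eq; enhanced mode only), cultivation (fertilizer and herbicide
production, field N₂O induced by applied nitrogen via a per-kg-N fraction,
and fruit transport to the mill), milling, biodiesel production
(transesterification inputs and CPO transport), POME (closed-system methane
capture and combustion, so the open-lagoon alternative is exactly
25/(44/16) ≈ 9.1-fold larger), biogenic combustion of biodiesel, fibre and
shell (water- and carbon-content corrected; enhanced mode only), annualized
land-use-change emissions E_LU = (CS_R − CS_A)/T · 3.664 with the measured
stocks 283.5 and 109.9 MgC ha⁻¹, and foregone forest sequestration
(−forest NEE × 3.664, default forest NEE −124 gC m⁻² yr⁻¹). Land-use change
and foregone sequestration are kept as separate components because whether
published land-use-change figures fold the two together is ambiguous;
reporting both lets either convention be recovered by addition. Traditional
mode zeroes the sink and biogenic components — the carbon-neutrality
assumption — and changes nothing else, so the two modes are comparable
term by term.

The background emission factors (fertilizer production, transport, milling,
transesterification, by-product fractions) live in a *foreground inventory*
fixture (`make_fixture_inventory("paper_defaults")`), with
representative literature-magnitude values and an explicit mill allocation
factor (default 1.0 to crude palm oil, since the heating values of kernel
co-products needed for a principled split are not available). The one
background value anchored to a reported number is the POME methane
inventory, chosen so the closed-system POME component is 1.8 gCO₂-eq MJ⁻¹.
Absolute per-MJ totals are therefore inventory-dependent; the package's
tested claims are the component structure, the conservation identity
(net = sum of components to machine precision), the traditional/enhanced
mode contract, the monotone decrease of land-use-change emissions with
longer amortization, and the scenario ordering (business-as-usual ≥ A ≥ B
for first-rotation nets). The fossil reference defaults to
94 gCO₂-eq MJ⁻¹, the EU renewable-energy-directive comparator.

## Monte Carlo uncertainty

`run_mc()` draws independent parameter sets (no Latin-hypercube or
correlation structure — plain Monte Carlo is what the analysis calls for),
evaluates a user model on each, and reports means, medians and the 25th/75th
percentiles of every output from 1000 iterations by default. Measured NEE
takes a normal distribution with a standard deviation of 5% of the value;
inventory-quality uncertainty uses lognormal factors from the pedigree
matrix, whose six-indicator score→factor table ships as a plain-text fixture
(`pedigree_table()`) and combines as gsd = exp(√Σ ln(f_i)²). Lognormal draws
treat the central value as the geometric mean (the inventory-database
convention). Model evaluations that error on a draw are excluded and
counted; more than 1% failures aborts the run — a policy chosen here, since
the source analysis is silent on failed draws.

## What the synthetic data do and do not show

`gen_halfhourly_nee()` produces a diurnal cycle as constant respiration in
every half-hour plus a half-sinusoid photosynthetic drawdown between 06:00
and 18:00, the baseline solved so the noise-free series integrates exactly
to the configured annual total (scaled by months/12 for partial years). The
defaults emulate the measured study conditions: a young-plantation source of
1012 gC m⁻² yr⁻¹ over 8 months, mature-plantation sinks of −799 and
−709 gC m⁻² yr⁻¹ over full years. Noise is multiplicative Gaussian and gaps
are placed uniformly at random in whole slots — the simplest model that
exercises the gap-filler. `gen_chamber_campaigns()` draws soil respiration
lognormally (strictly positive; arithmetic mean and CV preserved), CH₄ and
N₂O normally (both signs occur in the field), with the study's replicate and
campaign structure (4 mineral replicates × 45 campaigns, 2 peat
replicates × 37), a 2.6-fold peat/mineral respiration contrast on a
91.7 mgC m⁻² h⁻¹ mineral mean, a dispersion (CV) of 0.4, and N₂O pulses
decaying exponentially over a 14-day post-fertilization window (pulse
duration is unreported; 14 days with an e-folding time of one third of the
window is this package's choice). CH₄ is parametrized in µgC m⁻² h⁻¹; an
hourly "mg" unit sometimes printed for such fluxes is dimensionally
inconsistent with annual totals of order −0.13 gC m⁻² yr⁻¹ and is not
forced.

What passing tests show: the pipeline recovers known annual totals within
0.1% (clean) and 5% (20% gaps, gap-filled), recovers the configured
peat/mineral ratio within sampling error, and satisfies every arithmetic
identity. What they do not show: performance under real-world gap structure
(storm- and power-outage-clustered, not uniform), weather-driven seasonality
(the generator has none beyond the diurnal cycle), u*-filtering biases, or
spatial footprint effects — all upstream of this package's scope.

## Problem sizes and numerical notes

The test suite runs the full pipeline at the study's native sizes — 8- and
12-month half-hourly series (11,664–17,520 records), 45/37-campaign chamber
sets, 25–40-year cycles, 1000-iteration Monte Carlo — in a few seconds
total; nothing is scaled down. Degenerate inputs are rejected with
informative errors rather than coerced: non-uniform timesteps, partial
months, ≥ 50% gaps, single-campaign annualizations, zero yield in GHGI,
amortization periods ≤ 0, pedigree scores outside 1..5. Ties and edges:
gap-filling widens its window symmetrically and never changes a measured
value; trapezoid edge extension is constant; trajectory years are closed on
the plateau ends (year 3 is young, year 8 mature).

## Known limitations

No covariate-based gap-filling or friction-velocity screening; no peat-soil
LCA (soil fluxes on peat are supported, a full peat biodiesel chain is not);
no electricity-export credit for captured POME biogas; background emission
factors are fixtures, so absolute per-MJ totals should be re-derived with a
real background database before being quoted; and the decay curve's
exponential form is a modelling choice — its equilibrium values are robust
to the form, but trajectories in the first decade are not.
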