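---
title: "Methods: diet quality, food loss and waste, and agricultural footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet quality, food loss and waste, and agricultural footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietfootprint)
```

## What the package models

`dietfootprint` links three layers that are usually studied separately:

1. **Diet quality** of individuals from a 24-h recall, measured with the
   Healthy Eating Index 2015 (HEI-2015) and a modified Alternative Healthy
   Eating Index 2010 (AHEI-2010);
2. **Food loss and waste**: the retail loss, inedible portions and consumer
   waste implied by what people actually consumed, summed with consumption
   into *Total Food Demand*;
3. **Agricultural resources** — land by land-use category, fertilizer
   nutrients (N + P~2~O~5~ + K~2~O), pesticides, irrigation water — needed
   to produce that demand under a simplified closed-food-system biophysical
   model.

All estimation is design-based for a stratified multistage survey
(weighted means with Taylor-linearized variance, linear trend tests across
diet-quality quintiles), and uncertainty in the footprint is propagated by
Monte Carlo resampling of individuals.

Because the real input datasets (national recall surveys, recipe
databases, loss-availability series, agricultural survey parameters) are
large external resources, the package ships a seeded synthetic-data module
that emulates their statistical structure. Every stage is exercised end to
end on synthetic data; the national point estimates of the source datasets
are *not* reproducible at this scale and are not claimed.

## Diet-index scoring

Each index component is scored by piecewise-linear interpolation between a
zero-score threshold and a full-score threshold, clamped to
`[0, max_points]`. Adequacy components award more points for more intake;
moderation components are reverse scored. The standards ship as editable
CSV tables (`hei2015_standards()`, `ahei2010_standards()`) carrying the
published values, never hard-coded in logic, so the sensitivity analysis
(modified vs original AHEI) is a flag swap and alternative standards are a
file swap.

**Bases.** HEI-2015 components are scored on per-1000-kcal densities,
except the fatty-acid ratio ((PUFA+MUFA)/SFA) and the two
percent-of-energy components (added sugars, saturated fat), which are
scored as is. Under the *modified* AHEI-2010, every daily amount is
rescaled by `1849 / energy` — 1849 kcal/d being the mean energy intake of
the index's source population — before scoring; percent-of-energy amounts
are already energy-adjusted and are never rescaled. Component amounts
therefore enter the package in per-day units (cup/ounce equivalents,
servings, grams, milligrams) with the two percent-energy components and
the fatty-acid ratio carried directly on their scoring basis. This makes
the energy-scaling invariance exact: multiplying a record's intakes and
energy by the same factor leaves every density-based score unchanged.

**Alcohol.** Adults are scored on a two-sided trapezoid: non-drinkers
receive the published 2.5-point partial credit, points rise linearly to 10
at the lower band edge (0.5 drinks/d), hold through the moderate band
(up to 1.5 drinks/d for women, 2.0 for men), and fall linearly to zero at
heavy intake (2.5 / 3.5 drinks/d). Under the modified index, individuals
younger than 18 receive 10 points for zero *reported* consumption and 0
points for any consumption; the child rule operates on the raw amount,
not the energy-rescaled one, since "any consumption" is a fact about the
report, not about energy density.

**Sodium in AHEI-2010.** The original index scores sodium by cohort
deciles. Decile machinery would make scores a function of the sample; we
instead fix the thresholds in the standards table at the published decile
extremes (1112 mg/d for full credit, 3337 mg/d for zero). Users studying
decile-based scoring can regenerate the table from their own cohort.

**Population-ratio mean.** The population score is *not* the weighted mean
of individual scores: for each component the weighted total amount is
divided by the weighted total energy (rescaled to the component basis) and
that single population-level density is scored. Clamping makes the two
quantities differ, which the tests demonstrate on a two-person example.
For as-is components the population value is the energy-weighted mean
(the ratio of weighted totals when the amount is a percentage of energy;
an approximation for the fatty-acid ratio, where the underlying fat
totals are not carried separately). Sex-specific thresholds are resolved
to the weighted majority sex of the population.

**Quintiles.** Cutpoints are the weighted 20/40/60/80th percentiles,
defined as the left-continuous inverse of the weighted ECDF; scores tied
with a cutpoint fall in the lower quintile. This is deterministic and
matches common survey practice. Whether the original analyses formed
quintiles weighted or unweighted, per cycle or pooled, is not stated in
the source; weighted and pooled are the defaults, and `assign_quintiles()`
exposes the unweighted alternative.

**Degenerate energy.** Records reporting non-positive energy cannot be
scored on a density basis. The default policy excludes them with a logged
count; a strict policy errors. The generator never produces them (energy
has a hard floor), so the policy only matters for user-supplied data.

## Loss and waste accounting

Intake is observed and loss rates are forward fractions, so the mass
balance is computed *backwards* from consumed mass:

* consumer waste is a fraction `w` of edible purchased mass:
  `edible_purchased = consumed / (1 - w)`;
* inedible portions are a fraction `i` of purchased mass:
  `purchased = edible_purchased / (1 - i)`;
* retail loss is a fraction `r` of retail-level supply:
  `total_demand = purchased / (1 - r)`.

Category masses are recovered by subtraction, so the four categories sum
to Total Food Demand *exactly*, at every scope from one commodity to the
population. The chain order (retail, then inedible, then consumer) follows
the sequential structure of the loss-availability series this emulates;
applying `w` to edible purchased mass (rather than purchased mass
inclusive of inedible) is a known subtlety of that series and is the
convention adopted here. Commodities without a loss profile default to
zero loss with a warning (switchable to an error). All masses are carried
at full floating precision; rounding to integer grams happens only in
reports.

Pre-retail (farm and processing) losses are deliberately *not* part of
this chain: they live inside the footprint model's processing conversion
factors, so they are counted once, on the production side.

## Survey estimation

No survey package is assumed: the estimators are implemented directly.

* **Weighted mean**: the ratio `sum(w*x)/sum(w)`; variance by Taylor
  linearization (score contributions `w*(x - mean)/sum(w)`), totalled
  within PSUs, with between-PSU variation accumulated within strata as
  `n_h/(n_h - 1)` times the centred cross-products.
* **Trend tests**: weighted least squares of the outcome on the quintile
  index treated as a continuous 1–5 score (matching the "linear trend
  across quintiles" convention), with the design-based PSU-aggregated
  sandwich variance; optional age/sex adjustment appends covariates.
  Models are fit at the individual level (the source is silent on
  individual- vs summary-level fits; both are possible by aggregating
  first).
* **Wald difference tests**: the paired individual-level difference of
  two scorings analysed as a weighted mean; a zero linearized SE (e.g. a
  deterministic constant shift) is reported as degenerate with a warning.

Degrees of freedom are PSUs minus strata, the convention of standard
survey software; confidence intervals use the t distribution on that df.
A stratum with a single PSU aborts variance estimation and names the
stratum — public-use files of the survey this emulates guarantee two — and
estimates are exactly invariant to rescaling all weights.

Calibration is verified by simulation: under a null with no trend, the
test's type-I error at α = 0.05 stays within the binomial error band over
1000 seeded replicates, and a known per-quintile increment is covered by
its own 95% CI in at least 93% of replicates (the acceptance suite runs
both).

## The footprint model

The model represents the country as a closed food system: everything
consumed is produced domestically.

* **Import reapportionment.** Demand for commodities flagged as not
  produced domestically is redistributed within the food group. The
  redistribution weights are *fixed availability weights* from the
  parameter tables (an availability-series analogue) rather than the
  current demand vector. This was a genuine design choice: splitting
  proportionally to current demand is the more obvious reading, but it
  makes the operation nonlinear in demand, and the model's stream
  additivity (retail + inedible + waste + consumed = total) then only
  holds approximately. With fixed weights the whole chain is linear and
  additivity is exact; the demand-proportional split remains available by
  passing `availability = NULL`.
* **Demand to crops.** Plant foods are converted to primary-crop mass by
  processing conversions (which embed pre-retail losses); animal foods to
  carcass weight and then, through per-product feed vectors, to feed-grain
  and hay requirements, with livestock life phases collapsed into a single
  aggregate vector per product. Grazing enters as per-product pasture-area
  requirements divided by a single pasture-utilization scalar (default
  0.6), a deliberate simplification of finer grazing-land structure.
  Every conversion is recorded in an allocation ledger; multi-use crops
  are attributed to their co-products on a mass basis (allocated masses
  sum exactly to demanded mass), so acreage is never double-counted.
* **Crops to land**: requirement / yield, divided by the double-crop
  factor where one field produces multiple crops per year; land aggregates
  into the ten land-use categories (grains, fruits, vegetables, legumes,
  nuts, sweeteners, feed grains and oilseeds, hay, cropland pasture,
  permanent pasture).
* **Land to resources**: per-category application rates give fertilizer
  nutrients (N + P~2~O~5~ + K~2~O summed), pesticides, and irrigation
  water. Hay and pasture rates are low literature-style defaults, since
  agricultural surveys do not report them.
* **Attribution.** Because the chain is linear, running it once per
  loss/waste stream and normalising yields each stream's share of every
  resource; shares sum to one by construction.
* **Land check.** When available-land bounds are supplied, required land
  is reported against them with an exceedance flag; no optimisation or
  reallocation is attempted.

Units are fixed end to end: g/day per capita in, kg/yr and ha/yr at
population scale out (days-per-year 365); million-ha and billion-m³
rescaling happens only in report text.

**Monte Carlo.** Each replicate draws half the sample (default) without
replacement, with probability proportional to survey weight (the source
is silent on whether draws respect weights; weighted is the default and
unweighted is exposed), recomputes the weighted per-capita demand from
the subsample, reruns the chain, and scales to the population. Intervals
are the 2.5th/97.5th percentiles of 500 replicates by default — none of
these three values is stated by the source; they were chosen once as
conventional resampling settings. Everything is deterministic under a
fixed seed.

## The synthetic world

The generator emulates the structure the analysis assumes, not any real
dataset:

* a stratified design of 15 strata × 2 PSUs × 30 individuals with
  log-normal weights (log-sd 0.7), chosen to exercise weighted-vs-
  unweighted divergence;
* energy first (normal, mean 2100, sd 550, floor 500 kcal — a realistic
  adult-plus-children intake spread), then food grams conditional on
  energy, so each record's grams times per-food energy density sums
  exactly to its energy and density-based scoring is always defined;
* a latent healthfulness trait (PSU-clustered, gradient parameter 1) that
  tilts food shares toward the healthful food pool and adequacy component
  amounts upward, moderation downward — this is what produces correlated
  diet quality, demand, and footprints downstream;
* 5% of foods deliberately missing from the recipe table, emulating a
  recipe database that lags the recall instrument;
* commodity loss fractions drawn within realistic bands (retail 2–12%,
  inedible 0 or 5–45%, consumer waste 10–45%), always leaving a positive
  consumed share;
* a small agronomic parameter set with at least one non-domestic
  commodity (so reapportionment is always exercised), feed and grazing
  vectors for animal commodities, and a population size of 3.21 × 10⁸.

What the generator does **not** emulate: real food codes or commodity
names, multi-day recalls, measurement error and differential reporting,
seasonal or cyclic survey structure, or correlated loss rates across
commodities. A green test therefore establishes the correctness of the
computations and the calibration of the estimators on the stated world —
not agreement with any national point estimate.

## Numerical conventions

* Recipe fraction sums are validated to 1 ± 1e-6 and never silently
  renormalised; violations abort.
* Mass-balance additivity is asserted to 1e-6 g; the loss-chain round
  trip to 1e-9 relative; stream additivity of the footprint to 1e-6
  relative.
* Quintile ties at a cutpoint go to the lower quintile; fewer than five
  distinct scores degrade with a warning rather than an error.
* Seeds: every stochastic entry point takes an explicit integer seed;
  pipeline stages derive child seeds by small offsets from the master
  seed.

## Known limitations

Greenhouse-gas emissions, water scarcity, spatial and production-system
heterogeneity, organic-system detail, replicate-weight variance methods,
multiple-testing adjustment, and the carrying-capacity scenario machinery
of the full biophysical model are all out of scope. The trans-fat AHEI
component is excluded by design. The fatty-acid-ratio population score is
an energy-weighted approximation, as noted above.
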